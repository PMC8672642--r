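test_that("SAM records resolve CIGAR and mismatches against the reference", {
  genome <- c(chr1 = "ACGTACGTACGTACGTACGT")
  sam <- c("@HD\tVN:1.6",
           "@SQ\tSN:chr1\tLN:20",
           ## 4M matches, 2D deletes ref 7-8, 3M with mismatches, 1I, 4M
           paste("r1", 0, "chr1", 3, 60, "4M2D3M1I4M", "*", 0, 0,
                 "GTACACGGTACG", "*", sep = "\t"),
           paste("r2", 4, "chr1", 1, 0, "*", "*", 0, 0, "*", "*", sep = "\t"))
  tf <- tempfile(fileext = ".sam")
  writeLines(sam, tf)
  recs <- read_sam_records(tf, genome)
  expect_length(recs, 1L)  # unmapped r2 skipped
  r <- recs[[1]]
  expect_equal(r$start, 3L)
  expect_equal(r$end, 15L)
  expect_equal(r$del_pos, 7L)
  expect_equal(r$del_len, 2L)
  expect_equal(r$ins_pos, 11L)
  expect_equal(r$ins_len, 1L)
  ## ref 9-11 is ACG, read carries ACG -> no mismatches there;
  ## ref 12-15 TACG vs read TACG -> clean
  expect_length(r$sub_pos, 0L)
})

test_that("soft clips are skipped and mismatches located", {
  genome <- c(chr1 = "AAAACCCCGGGGTTTT")
  sam <- paste("r1", 0, "chr1", 5, 60, "2S4M3S", "*", 0, 0,
               "TTCGCCAAA", "*", sep = "\t")
  tf <- tempfile(fileext = ".sam")
  writeLines(sam, tf)
  r <- read_sam_records(tf, genome)[[1]]
  ## aligned read segment CGCC vs ref 5-8 CCCC: mismatch at ref 6
  expect_equal(r$sub_pos, 6L)
  expect_equal(r$sub_alt, "G")
})

test_that("the bundled aligner recovers known edits at toy scale", {
  genome <- make_toy_genome(1, 3000, seed = 17)
  tpl <- substr(genome[[1]], 501, 1500)
  read <- paste0(substr(tpl, 1, 399),
                 substr(tpl, 401, 700),      # delete template base 400
                 "GGGGG",                    # insert 5 bp after base 700
                 substr(tpl, 701, 1000))
  recs <- align_reads_to_reference(c(r1 = read), genome)
  r <- recs[[1]]
  expect_equal(r$start, 501L)
  ## indel placement may slide inside repeats; positions are near-exact
  expect_equal(sum(r$del_len), 1L)
  expect_lt(abs(r$del_pos - 900L), 10L)
  expect_equal(sum(r$ins_len), 5L)
  expect_lt(abs(r$ins_pos[1] - 1200L), 10L)
})

test_that("train-simulate-retrain closes on every context rate", {
  ## calibrated for the 192 simultaneous comparisons below: a per-rate
  ## 3 sigma bound would falsely fail ~40% of runs, |z| <= 4.5 about 0.1%
  p <- uniform_error_profile(0.05, 0.02, 0.03)
  genome <- make_toy_genome(1, 50000, seed = 19)
  cfg <- read_sim_config(coverage = 60, median_length = 2000,
                         length_range = c(500, 5000), seed = 19)
  sim <- simulate_reads(genome, p, cfg)
  tr <- train_profile(sim$records, genome)
  cnt <- attr(tr, "training")
  z <- function(est, p0, n) abs(est - p0) / sqrt(p0 * (1 - p0) / n)
  zs <- c(z(tr$contexts$sub_rate, 0.05, cnt$denom),
          z(tr$contexts$del_rate, 0.03, cnt$denom),
          z(tr$contexts$ins_rate, 0.02, cnt$emit_denom))
  expect_lt(max(zs), 4.5)
  expect_lt(abs(mean(zs) - sqrt(2 / pi)), 0.2)  # |N(0,1)| has mean ~0.8
  gt <- function(obs, prob) svforge:::g_test(obs, prob[seq_along(obs)])
  expect_gt(gt(cnt$ins_len_counts, p$ins_len_dist), 1e-4)
  expect_gt(gt(cnt$del_len_counts, p$del_len_dist), 1e-4)
})

test_that("training indels beyond l_max are clipped with a warning", {
  genome <- c(chr1 = strrep("ACGT", 200))
  rec <- aln_record("chr1", 1L, 800L, del_pos = 100L, del_len = 30L)
  expect_warning(p <- train_profile(list(rec), genome, l_max = 10L),
                 "clipped")
  expect_length(p$del_len_dist, 10L)
})

test_that("unseen contexts receive the genome-wide mean rate", {
  ## genome containing only A/C: G- and T-contexts are never observed
  genome <- c(chr1 = strrep("AACC", 250))
  rec <- aln_record("chr1", 1L, 1000L, sub_pos = 3L, sub_alt = "G")
  p <- train_profile(list(rec), genome)
  seen <- attr(p, "training")$denom > 0
  expect_true(any(!seen))
  m <- mean(p$contexts$sub_rate[seen])
  expect_true(all(p$contexts$sub_rate[!seen] == m))
})
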