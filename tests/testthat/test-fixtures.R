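test_that("toy genomes hit the requested GC and reproduce from the seed", {
  g <- make_toy_genome(1, 100000, gc = 0.5, seed = 61)
  gc <- sum(strsplit(g[[1]], "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc - 0.5), 0.01)
  g2 <- make_toy_genome(1, 100000, gc = 0.5, seed = 61)
  expect_identical(g, g2)
  pure <- make_toy_genome(1, 1000, gc = 1, seed = 62)
  expect_true(grepl("^[GC]+$", pure[[1]]))
  tf <- tempfile(fileext = ".fasta")
  make_toy_genome(2, 5000, seed = 63, path = tf)
  expect_equal(sum(nchar(svforge:::read_fasta(tf))), 10000L)
})

test_that("an identity pseudo-caller reproduces the truth exactly", {
  genome <- toy_ref(64, n_chroms = 1, length = 300000)
  truth <- toy_truth(genome, seed = 31, counts = c(DEL = 30, INS = 30))
  calls <- perturb_truth(truth, pseudo_caller_spec("ident", seed = 1), genome)
  rep <- benchmark_calls(calls, truth)
  expect_equal(rep$recall, 1)
  expect_equal(rep$precision, 1)
  expect_equal(rep$total_score, 100)
  expect_equal(rep$perfect_matches, nrow(truth))
})

test_that("false-negative and false-positive injection is bookkept", {
  genome <- toy_ref(65, n_chroms = 2, length = 500000)
  truth <- toy_truth(genome, seed = 32, counts = c(DEL = 100, INS = 100))
  spec <- pseudo_caller_spec("fn", fn_rate = 0.25, seed = 7)
  calls <- perturb_truth(truth, spec, genome)
  rep <- benchmark_calls(calls, truth)
  expect_equal(rep$tp, nrow(calls))     # every emitted call matches
  expect_equal(rep$fn, nrow(truth) - nrow(calls))
  ## all truth emitted exactly + FPs: the reported FP count is the injected
  ## count because no false positive can displace an exact match
  spec_fp <- pseudo_caller_spec("fp", fp_rate_per_mb = 50, seed = 8)
  calls_fp <- perturb_truth(truth, spec_fp, genome)
  injected <- nrow(calls_fp) - nrow(truth)
  expect_equal(injected, round(50 * sum(nchar(genome)) / 1e6))
  rep_fp <- benchmark_calls(calls_fp, truth)
  expect_equal(rep_fp$fp, injected)
  expect_equal(rep_fp$recall, 1)
})

test_that("pseudo-caller output is deterministic per seed", {
  genome <- toy_ref(66, n_chroms = 1, length = 100000)
  truth <- toy_truth(genome, seed = 33, counts = c(DEL = 20))
  spec <- pseudo_caller_spec("x", pos_jitter_sd = 50, fn_rate = 0.2,
                             fp_rate_per_mb = 30, seed = 9)
  expect_identical(perturb_truth(truth, spec, genome),
                   perturb_truth(truth, spec, genome))
})

test_that("the round trip reports every stage and reruns identically", {
  res <- run_roundtrip(seed = 77, n_chroms = 2, chrom_length = 200000,
                       coverage = 3,
                       sv_counts = c(DEL = 25, INS = 25, DUP = 5, INV = 5,
                                     CSUB = 5))
  expect_setequal(res$summary$call_set,
                  c("pbsv", "cuteSV", "Sniffles", "combined"))
  expect_equal(res$summary$tp + res$summary$fn, rep(nrow(res$truth), 4))
  ## consensus filtering beats the worst single caller on false positives
  singles <- res$summary[res$summary$call_set != "combined", ]
  combined <- res$summary[res$summary$call_set == "combined", ]
  expect_lte(combined$fp, min(singles$fp))
  res2 <- run_roundtrip(seed = 77, n_chroms = 2, chrom_length = 200000,
                        coverage = 3,
                        sv_counts = c(DEL = 25, INS = 25, DUP = 5, INV = 5,
                                      CSUB = 5))
  expect_identical(res$summary, res2$summary)
})

test_that("reads simulated from SV haplotypes cover the derived genome", {
  genome <- toy_ref(67, n_chroms = 1, length = 100000)
  truth <- toy_truth(genome, seed = 35, counts = c(DEL = 10, INS = 10))
  haps <- apply_svs(genome, truth)
  p <- uniform_error_profile(0.02, 0.01, 0.01)
  cfg <- read_sim_config(coverage = 5, median_length = 2000,
                         length_range = c(500, 5000), seed = 12)
  sim <- simulate_reads(list(hap1 = haps$hap1, hap2 = haps$hap2), p, cfg)
  genome_size <- mean(c(sum(nchar(haps$hap1)), sum(nchar(haps$hap2))))
  span <- sum(sim$truth$end - sim$truth$start + 1)
  expect_lt(abs(span / genome_size - 5) / 5, 0.05)
})
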