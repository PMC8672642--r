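test_that("each rearrangement type edits the sequence as expected", {
  one <- function(ref, ...) {
    ev <- sv_events(data.frame(..., stringsAsFactors = FALSE), toy = TRUE)
    apply_svs(c(chr1 = ref), ev, toy = TRUE)$hap1[["chr1"]]
  }
  expect_equal(one("AACCGGTTAA", chrom = "chr1", start = 3,
                   sv_type = "DEL", length = 4), "AATTAA")
  expect_equal(one("AAAAA", chrom = "chr1", start = 2, sv_type = "INS",
                   length = 3, inserted_seq = "GGG"), "AAGGGAAA")
  expect_equal(one("ATCGTTTT", chrom = "chr1", start = 1, sv_type = "DUP",
                   length = 4), "ATCGATCGTTTT")
  expect_equal(one("ATCGTTTT", chrom = "chr1", start = 1,
                   sv_type = "INVDUP", length = 4), "ATCGCGATTTTT")
  ## a reverse-complement palindrome inverts to itself
  expect_equal(one("AACGTT", chrom = "chr1", start = 2, sv_type = "INV",
                   length = 4), "AACGTT")
  ## complex substitution = deletion composed with an insertion
  expect_equal(one("AACCGGTTAA", chrom = "chr1", start = 3, sv_type = "CSUB",
                   length = 5, ref_span = 4, inserted_seq = "TTTTT"),
               "AATTTTTTTAA")
})

test_that("reciprocal translocation exchanges chromosome tails", {
  ref <- c(chrA = "AAAAACCCCC", chrB = "GGGGGTTTTT")
  ev <- sv_events(data.frame(chrom = "chrA", start = 6, sv_type = "TRA",
                             length = 5, ref_span = 5, chrom2 = "chrB",
                             pos2 = 6, stringsAsFactors = FALSE), toy = TRUE)
  out <- apply_svs(ref, ev, toy = TRUE)$hap1
  expect_equal(out[["chrA"]], "AAAAATTTTT")
  expect_equal(out[["chrB"]], "GGGGGCCCCC")
})

test_that("haplotype lengths obey exact per-event bookkeeping", {
  genome <- toy_ref(9, n_chroms = 2, length = 60000)
  for (seed in 1:20) {
    ev <- toy_truth(genome, seed = seed,
                    counts = c(DEL = 8, INS = 8, DUP = 3, INVDUP = 2,
                               INV = 2, CSUB = 3))
    res <- apply_svs(genome, ev)
    for (sel in list(c("hap1", "HET_H2"), c("hap2", "HET_H1"))) {
      e <- ev[ev$genotype != sel[2], ]
      expect_identical(sum(nchar(res[[sel[1]]])),
                       sum(nchar(genome)) + sum(sv_length_delta(e)))
    }
    expect_identical(sum(nchar(res$merged)),
                     sum(nchar(genome)) + sum(sv_length_delta(ev)))
  }
})

test_that("HOM events land on both haplotypes, HET on exactly one", {
  genome <- toy_ref(12, n_chroms = 1, length = 20000)
  ev <- sv_events(data.frame(
    chrom = "chr1", start = c(2000, 8000, 14000),
    sv_type = "DEL", length = 100,
    genotype = c("HOM", "HET_H1", "HET_H2"), stringsAsFactors = FALSE))
  res <- apply_svs(genome, ev)
  expect_equal(nchar(res$hap1[[1]]), 20000 - 200)  # HOM + HET_H1
  expect_equal(nchar(res$hap2[[1]]), 20000 - 200)  # HOM + HET_H2
  expect_equal(nchar(res$merged[[1]]), 20000 - 300)  # everything
})

test_that("overlapping events on one haplotype are refused", {
  genome <- toy_ref(13, n_chroms = 1, length = 5000)
  ev <- sv_events(data.frame(chrom = "chr1", start = c(1000, 1020),
                             sv_type = "DEL", length = 60,
                             stringsAsFactors = FALSE))
  expect_error(apply_svs(genome, ev), "overlapping")
})

test_that("realignment around indel breakpoints recovers the event length", {
  ## brute-force oracle: globally align the derived haplotype back to the
  ## reference and read the indel length out of the alignment
  genome <- make_toy_genome(1, 2000, seed = 21)
  for (case in list(c("DEL", 120), c("INS", 90))) {
    ty <- case[1]; len <- as.integer(case[2])
    seq <- if (ty == "INS") substr(strrep("ACGT", len), 1, len) else ""
    ev <- sv_events(data.frame(
      chrom = "chr1", start = 900, sv_type = ty, length = len,
      inserted_seq = seq, stringsAsFactors = FALSE), toy = TRUE)
    hap <- apply_svs(genome, ev, toy = TRUE)$hap1[[1]]
    aln <- Biostrings::pairwiseAlignment(hap, genome[[1]], type = "global")
    ind <- if (ty == "DEL") {
      Biostrings::deletion(Biostrings::nindel(aln))
    } else {
      Biostrings::insertion(Biostrings::nindel(aln))
    }
    expect_equal(unname(ind[1, "WidthSum"]), len)
  }
})
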