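test_that("the confirmation threshold resolves from the input count", {
  expect_equal(resolve_min_callers(2), 2L)
  expect_equal(resolve_min_callers(5), 2L)
  expect_equal(resolve_min_callers(6), 3L)
  expect_equal(resolve_min_callers(6, combine_config(min_callers = 2)), 2L)
})

test_that("loading drops records below the alt-coverage floor", {
  genome <- toy_ref(51, n_chroms = 1, length = 200000)
  truth <- toy_truth(genome, seed = 21, counts = c(DEL = 20, INS = 20))
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  perturb_truth(truth, pseudo_caller_spec("cuteSV", support = 2, seed = 1),
                genome, out = f1)
  perturb_truth(truth, pseudo_caller_spec("pbsv", support = 10, seed = 2),
                genome, out = f2)
  calls <- load_caller_vcfs(c(cuteSV = f1, pbsv = f2))
  expect_true(all(calls$caller == "pbsv"))  # support-2 records dropped
  expect_error(load_caller_vcfs(c(cuteSV = f1)), "at least 2")
  expect_warning(load_caller_vcfs(setNames(c(f1, f2), c("a", "b"))),
                 "not recommended")
})

test_that("clustering groups concordant calls and splits distant ones", {
  cc <- combine_config()
  calls <- rbind(call_row(10000, caller = "pbsv"),
                 call_row(10050, caller = "cuteSV"),
                 call_row(9950, caller = "Sniffles"),
                 call_row(15000, caller = "pbsv"))
  g <- cluster_calls(calls, cc)
  expect_equal(g[1], g[2])
  expect_equal(g[1], g[3])
  expect_false(g[4] == g[1])
  ## two calls from one caller near one locus: nearest joins, other splits
  dup <- rbind(call_row(10000, caller = "pbsv"),
               call_row(10100, caller = "cuteSV"),
               call_row(10900, caller = "cuteSV"))
  gd <- cluster_calls(dup, cc)
  expect_equal(gd[1], gd[2])
  expect_false(gd[3] == gd[1])
  ## incompatible lengths never share a group
  far <- rbind(call_row(10000, length = 1000, caller = "pbsv"),
               call_row(10010, length = 200, caller = "cuteSV"))
  expect_false(do.call(identical, as.list(cluster_calls(far, cc))))
})

test_that("group resolution applies per-statistic caller priorities", {
  cc <- combine_config()
  grp <- rbind(call_row(10000, length = 480, caller = "pbsv",
                        genotype = "het"),
               call_row(10030, length = 500, caller = "cuteSV",
                        genotype = "hom"),
               call_row(10060, length = 520, caller = "Sniffles",
                        genotype = "het"))
  res <- resolve_group(grp, 2, cc)
  expect_equal(res$pos, 10000L)        # pbsv leads position/length
  expect_equal(res$length, 480L)
  expect_equal(res$genotype, "hom")    # cuteSV leads genotype
  expect_equal(res$n_callers, 3L)
  ## BND types defer to the highest-priority caller with a resolved type
  grp2 <- rbind(call_row(10000, length = 0, caller = "pbsv",
                         sv_type = "BND"),
                call_row(10030, length = 500, caller = "cuteSV",
                         sv_type = "DEL"))
  expect_equal(resolve_group(grp2, 2, cc)$sv_type, "DEL")
})

test_that("rescue rules admit known-reliable singletons only", {
  cc <- combine_config()
  expect_false(is.null(resolve_group(
    call_row(1000, caller = "SVIM", sv_type = "INV", genotype = "hom"),
    2, cc)))
  expect_false(is.null(resolve_group(
    call_row(1000, caller = "Sniffles", sv_type = "INS", genotype = "het"),
    2, cc)))
  expect_false(is.null(resolve_group(
    call_row(1000, caller = "Sniffles", sv_type = "DEL", genotype = "het"),
    2, cc)))
  expect_null(resolve_group(
    call_row(1000, caller = "Sniffles", sv_type = "INV", genotype = "het"),
    2, cc))
  expect_null(resolve_group(
    call_row(1000, caller = "NanoVar", sv_type = "DEL", genotype = "het"),
    2, cc))
  off <- combine_config(no_singletons = TRUE)
  expect_null(resolve_group(
    call_row(1000, caller = "SVIM", sv_type = "INV", genotype = "hom"),
    2, off))
})

test_that("identical calls from every caller collapse to one record", {
  calls <- do.call(rbind, lapply(c("pbsv", "cuteSV", "Sniffles"),
                                 function(cl) call_row(5000, caller = cl)))
  res <- combine_sv_calls(calls)
  expect_equal(nrow(res), 1L)
  expect_equal(res$callers, "Sniffles,cuteSV,pbsv")
})

test_that("disjoint singletons without rescue yield an empty VCF", {
  calls <- rbind(call_row(5000, caller = "pbsv", genotype = "het"),
                 call_row(50000, caller = "cuteSV", genotype = "het"))
  out <- tempfile(fileext = ".vcf")
  res <- combine_sv_calls(calls, combine_config(no_singletons = TRUE),
                          out = out)
  expect_equal(nrow(res), 0L)
  lines <- readLines(out)
  expect_true(all(startsWith(lines, "#")))
  expect_equal(nrow(read_caller_vcf(out)), 0L)
})

test_that("combining a consensus with itself is idempotent", {
  genome <- toy_ref(52, n_chroms = 2, length = 300000)
  truth <- toy_truth(genome, seed = 23, counts = c(DEL = 40, INS = 40))
  calls <- do.call(rbind, lapply(default_pseudo_panel(3), function(sp) {
    perturb_truth(truth, sp, genome)
  }))
  res1 <- combine_sv_calls(calls)
  out <- tempfile(fileext = ".vcf")
  write_combined_vcf(res1, out)
  again <- rbind(read_caller_vcf(out, "copyA"),
                 read_caller_vcf(out, "copyB"))
  res2 <- combine_sv_calls(again)
  cols <- c("chrom", "pos", "length", "sv_type", "genotype")
  expect_equal(res1[, cols], res2[, cols])
})

test_that("dropping a non-priority caller keeps confirmed records stable", {
  calls <- rbind(call_row(10000, caller = "pbsv"),
                 call_row(10040, caller = "cuteSV"),
                 call_row(10080, caller = "NanoSV"),
                 call_row(90000, caller = "cuteSV"),
                 call_row(90100, caller = "NanoSV"))
  full <- combine_sv_calls(calls)
  reduced <- combine_sv_calls(calls[calls$caller != "NanoSV", ])
  shared <- full[full$pos %in% reduced$pos, c("pos", "length")]
  expect_equal(reduced[reduced$pos %in% shared$pos, c("pos", "length")],
               shared)
})
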