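test_that("call filtering enforces PASS, length and support floors", {
  cfg <- benchmark_config()
  calls <- rbind(call_row(1000, length = 49, support = 10),
                 call_row(2000, length = 500, support = 2),
                 call_row(3000, length = 500, support = 10,
                          filter = "q5"),
                 call_row(4000, length = 500, support = 10),
                 call_row(5000, length = 0, support = 10),   # undetermined
                 call_row(6000, length = 500, support = NA), # no field
                 call_row(7000, length = 500, filter = "."))
  kept <- filter_calls(calls, cfg)
  expect_equal(kept$pos, c(4000L, 5000L, 6000L, 7000L))
  cfg30 <- benchmark_config(min_support = 5L)
  expect_equal(nrow(filter_calls(call_row(1000, support = 4), cfg30)), 0L)
})

test_that("matching follows the position window and length margins", {
  truth <- truth_row(10000, length = 500)
  ## dpos 800 <= 1600 and dlen 100 <= 0.35*500: match
  m1 <- match_calls(call_row(10800, length = 600), truth)
  expect_equal(nrow(m1$matches), 1L)
  ## dpos 2000 > 1600: false positive plus false negative
  m2 <- match_calls(call_row(12000, length = 600), truth)
  expect_equal(nrow(m2$matches), 0L)
  expect_length(m2$fp, 1L)
  expect_length(m2$fn, 1L)
  ## short SVs tolerate no length error
  short <- truth_row(10000, length = 100)
  m3 <- match_calls(call_row(10000, length = 101), short)
  expect_equal(nrow(m3$matches), 0L)
  m4 <- match_calls(call_row(10000, length = 100), short)
  expect_equal(nrow(m4$matches), 1L)
  ## undetermined length matches on position alone, with no length credit
  m5 <- match_calls(call_row(10050, length = 0, sv_type = "BND"), truth)
  expect_equal(nrow(m5$matches), 1L)
  expect_equal(m5$matches$len_score, 0)
  ## type and genotype never gate matching
  m6 <- match_calls(call_row(10000, length = 500, sv_type = "INS",
                             genotype = "het"), truth)
  expect_equal(nrow(m6$matches), 1L)
  expect_false(m6$matches$type_correct)
})

test_that("per-call scores follow the weighted decay scheme", {
  truth <- truth_row(10000, length = 500)
  exact <- match_calls(call_row(10000, length = 500), truth)
  expect_identical(score_call(exact$matches), 1)
  half <- match_calls(call_row(10800, length = 500), truth)
  expect_equal(score_call(half$matches), 0.8)  # 0.4*0.5 + 0.2+0.2+0.2
  gt_wrong <- match_calls(call_row(10000, length = 500, genotype = "het"),
                          truth)
  expect_equal(score_call(gt_wrong$matches), 0.8)
  fp_only <- match_calls(call_row(14000), truth)
  expect_error(score_call(fp_only$matches), "matched")
})

test_that("summary metrics follow the printed formulas", {
  truth <- do.call(rbind, lapply(seq_len(100), function(i) {
    truth_row(20000 * i, length = 500)
  }))
  truth <- sv_events(truth, toy = TRUE)
  hits <- do.call(rbind, lapply(seq_len(50), function(i) {
    call_row(20000 * i, length = 500)
  }))
  fps <- do.call(rbind, lapply(seq_len(50), function(i) {
    call_row(20000 * i + 10000, length = 500)
  }))
  rep <- benchmark_calls(rbind(hits, fps), truth)
  expect_equal(rep$tp, 50L)
  expect_equal(rep$fp, 50L)
  expect_equal(rep$fn, 50L)
  expect_equal(rep$recall, 0.5)
  expect_equal(rep$precision, 0.5)
  expect_equal(rep$f_score, 2 * ((0.5 * 0.5) / (0.5 + 0.5)))
  ## 50 perfect scores minus 50 false positives over 100 truth SVs
  expect_equal(rep$total_score, 0)
  none <- match_calls(call_row(1, length = 500)[0, ], truth)
  m0 <- compute_metrics(none, truth, call_row(1)[0, ])
  expect_equal(m0$recall, 0)
  expect_equal(m0$precision, 0)
  expect_equal(m0$f_score, 0)
})

test_that("matched, FP and FN counts are conserved", {
  genome <- toy_ref(41, n_chroms = 2, length = 300000)
  truth <- toy_truth(genome, seed = 13,
                     counts = c(DEL = 60, INS = 60))
  spec <- pseudo_caller_spec("jit", pos_jitter_sd = 300,
                             len_jitter_frac = 0.2, fn_rate = 0.15,
                             fp_rate_per_mb = 20, seed = 5)
  calls <- perturb_truth(truth, spec, genome)
  matched <- match_calls(calls, truth)
  expect_identical(nrow(matched$matches) + length(matched$fn), nrow(truth))
  expect_identical(nrow(matched$matches) + length(matched$fp), nrow(calls))
})

test_that("position sub-scores track the injected jitter", {
  ## oracle: expected position credit is the mean linear decay over the
  ## realized |dpos| sample itself
  genome <- toy_ref(42, n_chroms = 1, length = 2000000)
  truth <- toy_truth(genome, seed = 14, counts = c(DEL = 150))
  spec <- pseudo_caller_spec("jit", pos_jitter_sd = 400, seed = 6)
  calls <- perturb_truth(truth, spec, genome)
  matched <- match_calls(calls, truth)
  dpos <- abs(calls$pos[matched$matches$call] -
                truth$start[matched$matches$truth])
  oracle <- 0.4 * mean(pmax(0, 1 - dpos / 1600))
  expect_equal(mean(matched$matches$pos_score), oracle, tolerance = 1e-12)
  expect_lt(abs(mean(matched$matches$pos_score) -
                  0.4 * (1 - mean(dpos) / 1600)), 0.02)
})

test_that("matching is invariant under coordinate translation", {
  truth <- sv_events(do.call(rbind, lapply(c(10000, 30000, 60000),
                                           function(s) {
    truth_row(s, length = 400)
  })), toy = TRUE)
  calls <- rbind(call_row(10200, length = 400),
                 call_row(30500, length = 420),
                 call_row(64000, length = 400))
  before <- match_calls(calls, truth)
  shift <- 12345L
  truth2 <- truth; truth2$start <- truth2$start + shift
  calls2 <- calls; calls2$pos <- calls2$pos + shift
  after <- match_calls(calls2, sv_events(truth2, toy = TRUE))
  expect_equal(before$matches$score, after$matches$score)
  expect_equal(before$fp, after$fp)
  expect_equal(before$fn, after$fn)
})
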