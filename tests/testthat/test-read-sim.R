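test_that("read lengths honour the degenerate and median contracts", {
  cfg <- read_sim_config(coverage = 1, median_length = 1000,
                         length_range = c(1000, 1000), seed = 1)
  expect_true(all(sample_read_length(cfg, 100) == 1000L))
  cfg2 <- read_sim_config(coverage = 1, median_length = 25000,
                          length_range = c(5000, 80000), seed = 1)
  set.seed(3)
  lens <- sample_read_length(cfg2, 50000)
  expect_true(all(lens >= 5000 & lens <= 80000))
  expect_lt(abs(stats::median(lens) - 25000) / 25000, 0.02)
  set.seed(9); a <- sample_read_length(cfg2, 100)
  set.seed(9); b <- sample_read_length(cfg2, 100)
  expect_identical(a, b)
})

test_that("uniform read starts pass a chi-square uniformity check", {
  set.seed(5)
  starts <- sample_read_start(10000L, 1L, n = 20000L)
  expect_true(all(starts >= 1 & starts <= 10000))
  counts <- tabulate(ceiling(starts / 1000), 10)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("depth-profile sampling is proportional to window depth", {
  dp <- data.frame(chrom = "chr1", start = c(1, 5001),
                   end = c(5000, 10000), depth = c(10, 30))
  set.seed(6)
  starts <- sample_read_start(10000L, 1L, depth_profile = dp, n = 40000L)
  ratio <- sum(starts > 5000) / sum(starts <= 5000)
  expect_lt(abs(ratio - 3) / 3, 0.1)
  dp0 <- data.frame(chrom = "chr1", start = c(1, 5001),
                    end = c(5000, 10000), depth = c(0, 10))
  starts0 <- sample_read_start(10000L, 1L, depth_profile = dp0, n = 1000L)
  expect_true(all(starts0 > 5000))
})

test_that("corruption follows the profile exactly in the limits", {
  template <- make_toy_genome(1, 5000, seed = 3)[[1]]
  zero <- uniform_error_profile(0, 0, 0)
  set.seed(1)
  out <- corrupt_sequence(template, zero)
  expect_identical(out$read, template)
  expect_length(out$sub_pos, 0)
  expect_length(out$del_pos, 0)
  all_sub <- uniform_error_profile(1, 0, 0)
  set.seed(2)
  forced <- corrupt_sequence(template, all_sub)
  expect_equal(nchar(forced$read), nchar(template))
  mid <- 2:(nchar(template) - 1)
  expect_true(all(mid %in% forced$sub_pos))
})

test_that("realized error rates match the profile within binomial noise", {
  p <- uniform_error_profile(0.05, 0.02, 0.03)
  template <- make_toy_genome(1, 1000000, seed = 8)[[1]]
  set.seed(4)
  out <- corrupt_sequence(template, p)
  n <- nchar(template)
  for (chk in list(list(length(out$sub_pos), 0.05),
                   list(length(out$ins_pos), 0.02),
                   list(length(out$del_pos), 0.03))) {
    rate <- chk[[1]] / n
    ## deletions consume bases, so slightly fewer positions draw events;
    ## allow that depletion (~d*E[L] ~ 4%) on top of 3 sigma binomial noise
    se <- sqrt(chk[[2]] * (1 - chk[[2]]) / n)
    expect_lt(abs(rate - chk[[2]]), 3 * se + 0.045 * chk[[2]])
  }
})

test_that("total yield tracks requested coverage", {
  genome <- toy_ref(22, n_chroms = 1, length = 100000)
  p <- uniform_error_profile(0.02, 0.01, 0.01)
  cfg <- read_sim_config(coverage = 20, median_length = 2000,
                         length_range = c(500, 5000), seed = 2)
  sim <- simulate_reads(genome, p, cfg)
  span <- sum(sim$truth$end - sim$truth$start + 1)
  expect_gt(span, 1.9e6)
  expect_lt(span, 2.1e6)
  empty <- simulate_reads(genome, p,
                          read_sim_config(coverage = 0, median_length = 2000,
                                          length_range = c(500, 5000),
                                          seed = 2))
  expect_equal(nrow(empty$truth), 0L)
})

test_that("accuracy override sets the mean read identity", {
  genome <- toy_ref(23, n_chroms = 1, length = 100000)
  p <- uniform_error_profile(0.05, 0.02, 0.03)
  cfg <- read_sim_config(coverage = 10, median_length = 2000,
                         length_range = c(500, 5000), seed = 3,
                         accuracy_override = 0.99)
  sim <- simulate_reads(genome, p, cfg)
  tlen <- sim$truth$end - sim$truth$start + 1
  ident <- 1 - (sim$truth$n_sub + sim$truth$n_ins + sim$truth$n_del) / tlen
  expect_lt(abs(mean(ident) - 0.99), 0.01)
})

test_that("simulation output is byte-identical for a fixed seed", {
  genome <- toy_ref(24, n_chroms = 2, length = 20000)
  p <- uniform_error_profile(0.05, 0.02, 0.03)
  cfg <- read_sim_config(coverage = 3, median_length = 2000,
                         length_range = c(500, 5000), seed = 7)
  f1 <- tempfile(); f2 <- tempfile()
  simulate_reads(list(genome, genome), p, cfg, out_prefix = f1)
  simulate_reads(list(genome, genome), p, cfg, out_prefix = f2)
  expect_identical(readLines(paste0(f1, ".fastq")),
                   readLines(paste0(f2, ".fastq")))
  expect_identical(readLines(paste0(f1, "_truth.tsv")),
                   readLines(paste0(f2, "_truth.tsv")))
})

test_that("reads sample both haplotypes and both strands evenly", {
  genome <- toy_ref(25, n_chroms = 1, length = 50000)
  p <- uniform_error_profile(0.01, 0.005, 0.005)
  cfg <- read_sim_config(coverage = 30, median_length = 1000,
                         length_range = c(500, 2000), seed = 11)
  sim <- simulate_reads(list(h1 = genome, h2 = genome), p, cfg)
  n <- nrow(sim$truth)
  expect_gt(n, 800)
  for (frac in c(mean(sim$truth$hap == "h1"),
                 mean(sim$truth$strand == "+"))) {
    expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
  }
})
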