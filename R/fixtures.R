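#' Generate a reproducible random toy genome
#'
#' @param n_chroms number of chromosomes
#' @param length length of each chromosome (bp, >= 1000)
#' @param gc GC content in [0, 1]
#' @param seed integer seed
#' @param path optional FASTA output path
#' @return named character vector of chromosome sequences (invisibly writes
#'   FASTA when `path` is given)
#' @export
make_toy_genome <- function(n_chroms = 1L, length = 100000L, gc = 0.5,
                            seed = 1L, path = NULL) {
  stopifnot(length >= 1000L, gc >= 0, gc <= 1)
  genome <- with_seed(derive_seed(seed, "toy-genome"), {
    setNames(vapply(seq_len(n_chroms), function(i) {
      int_to_dna(sample_bases_int(length, gc))
    }, character(1)), paste0("chr", seq_len(n_chroms)))
  })
  if (!is.null(path)) write_fasta(genome, path)
  genome
}

#' Specification of a pseudo-caller
#'
#' A pseudo-caller perturbs a truth set into a caller-style call set with
#' controlled error modes, emulating qualitatively the failure modes of real
#' SV callers (missed events, breakpoint jitter, length error, genotype
#' flips, type confusion such as insertions typed as duplications, and
#' uniform false positives).
#'
#' @param name caller label
#' @param pos_jitter_sd Gaussian breakpoint jitter (bp)
#' @param len_jitter_frac multiplicative length jitter (fractional sd)
#' @param fn_rate probability of dropping each truth event
#' @param fp_rate_per_mb false positives injected per Mb of genome
#'   (deterministic count: `round(rate * Mb)`)
#' @param gt_error_rate probability of flipping het/hom
#' @param type_confusion optional data.frame (from, to, prob)
#' @param support constant supporting-read count stamped on emitted calls
#' @param seed integer seed
#' @return list of class `pseudo_caller_spec`
#' @export
pseudo_caller_spec <- function(name = "pseudo", pos_jitter_sd = 0,
                               len_jitter_frac = 0, fn_rate = 0,
                               fp_rate_per_mb = 0, gt_error_rate = 0,
                               type_confusion = NULL, support = 10L,
                               seed = 1L) {
  rates <- c(fn_rate, gt_error_rate)
  stopifnot(all(rates >= 0 & rates <= 1), fp_rate_per_mb >= 0)
  structure(list(name = name, pos_jitter_sd = pos_jitter_sd,
                 len_jitter_frac = len_jitter_frac, fn_rate = fn_rate,
                 fp_rate_per_mb = fp_rate_per_mb,
                 gt_error_rate = gt_error_rate,
                 type_confusion = type_confusion,
                 support = as.integer(support), seed = as.integer(seed)),
            class = "pseudo_caller_spec")
}

#' Perturb a truth set into a pseudo-caller call set
#'
#' Each truth event is independently dropped at the false-negative rate,
#' otherwise emitted with Gaussian position jitter, multiplicative length
#' jitter, genotype flips and type confusion; false positives are added
#' uniformly over the genome at the configured per-Mb rate. Deterministic
#' for a fixed spec seed.
#'
#' @param truth SV event data.frame
#' @param spec a [pseudo_caller_spec()]
#' @param genome named character vector (for genome size and FP placement)
#' @param out optional VCF output path
#' @return call-record data.frame (same shape as [read_caller_vcf()])
#' @export
perturb_truth <- function(truth, spec, genome, out = NULL) {
  genome <- as_seq_set(genome)
  lens <- nchar(genome)
  with_seed(derive_seed(spec$seed, paste0("pseudo-", spec$name)), {
    n <- nrow(truth)
    kept <- runif(n) >= spec$fn_rate
    tt <- truth[kept, , drop = FALSE]
    m <- nrow(tt)
    pos <- tt$start + as.integer(round(rnorm(m, 0, spec$pos_jitter_sd)))
    pos <- pmax(1L, pmin(pos, lens[tt$chrom]))
    len <- as.integer(round(tt$length *
                              pmax(0.01, 1 + rnorm(m, 0, spec$len_jitter_frac))))
    gt <- ifelse(tt$genotype == "HOM", "hom", "het")
    flip <- runif(m) < spec$gt_error_rate
    gt[flip] <- ifelse(gt[flip] == "hom", "het", "hom")
    ty <- tt$sv_type
    if (!is.null(spec$type_confusion)) {
      for (i in seq_len(nrow(spec$type_confusion))) {
        hit <- ty == spec$type_confusion$from[i] &
          runif(m) < spec$type_confusion$prob[i]
        ty[hit] <- spec$type_confusion$to[i]
      }
    }
    calls <- data.frame(caller = spec$name, chrom = tt$chrom, pos = pos,
                        length = len, sv_type = ty, genotype = gt,
                        support = spec$support, filter = "PASS",
                        stringsAsFactors = FALSE)
    n_fp <- round(spec$fp_rate_per_mb * sum(lens) / 1e6)
    if (n_fp > 0) {
      ci <- sample.int(length(lens), n_fp, replace = TRUE, prob = lens)
      fp_len <- rloguniform(n_fp, 50, 2000)
      fp <- data.frame(caller = spec$name, chrom = names(lens)[ci],
                       pos = as.integer(ceiling(runif(n_fp) * lens[ci])),
                       length = fp_len,
                       sv_type = sample(c("DEL", "INS"), n_fp, replace = TRUE),
                       genotype = sample(c("het", "hom"), n_fp,
                                         replace = TRUE),
                       support = spec$support, filter = "PASS",
                       stringsAsFactors = FALSE)
      calls <- rbind(calls, fp)
    }
    calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
    rownames(calls) <- NULL
    if (!is.null(out)) write_call_vcf(calls, out, source = spec$name)
    calls
  })
}

#' Write generic call records as a caller-style VCF
#'
#' Symbolic-ALT records with SVTYPE/SVLEN/END/SUPPORT INFO keys and a GT
#' sample column; round-trips through [read_caller_vcf()].
#'
#' @param calls call-record data.frame
#' @param path output path
#' @param source value of the `##source=` header line
#' @return the path, invisibly
#' @export
write_call_vcf <- function(calls, path, source = "svforge") {
  extra <- '##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description="Supporting reads">'
  gt <- ifelse(calls$genotype == "hom", "1/1",
               ifelse(calls$genotype == "het", "0/1", "./."))
  end <- calls$pos + ifelse(calls$sv_type == "INS", 0L,
                            pmax(calls$length - 1L, 0L))
  info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", calls$sv_type,
                  ifelse(calls$sv_type == "DEL", -calls$length, calls$length),
                  end)
  has_sup <- !is.na(calls$support)
  info[has_sup] <- paste0(info[has_sup], ";SUPPORT=", calls$support[has_sup])
  rec <- data.frame(chrom = calls$chrom, pos = calls$pos,
                    id = sprintf("call%06d", seq_len(nrow(calls))),
                    ref = "N", alt = paste0("<", calls$sv_type, ">"),
                    qual = ".", filter = calls$filter, info = info,
                    format = "GT", sample = gt, stringsAsFactors = FALSE)
  write_vcf_lines(vcf_header(NULL, extra, sample = "PSEUDO",
                             source = source), rec, path)
}

#' Run the full simulate-call-benchmark-combine round trip
#'
#' Drives every stage of the package on synthetic data: toy genome, random
#' SV truth set, diploid haplotypes, long-read simulation, a panel of
#' pseudo-callers, per-caller benchmarking, consensus combination, and a
#' benchmark of the combined set with the same configuration.
#'
#' @param seed master seed; each stage derives its own sub-seed
#' @param n_chroms,chrom_length,gc toy genome parameters
#' @param sv_counts named vector for [sv_sim_config()]
#' @param sv_length_range length_range for [sv_sim_config()]
#' @param coverage fold-coverage for read simulation (0 skips reads)
#' @param profile error profile for read simulation
#' @param read_config optional [read_sim_config()] override
#' @param pseudo_callers list of [pseudo_caller_spec()]s
#' @param bench a [benchmark_config()]
#' @param combine a [combine_config()]
#' @param out_dir optional directory for TSV/text reports
#' @return list with `truth`, `read_stats`, `benchmarks` (per caller +
#'   combined), and `summary` (one data.frame row per call set)
#' @export
run_roundtrip <- function(seed = 1L, n_chroms = 2L, chrom_length = 500000L,
                          gc = 0.45,
                          sv_counts = c(DEL = 40, INS = 40, DUP = 10,
                                        INV = 5, CSUB = 5),
                          sv_length_range = list(default = c(50, 2000)),
                          coverage = 5,
                          profile = uniform_error_profile(0.03, 0.01, 0.02),
                          read_config = NULL,
                          pseudo_callers = default_pseudo_panel(seed),
                          bench = benchmark_config(),
                          combine = combine_config(),
                          out_dir = NULL) {
  genome <- make_toy_genome(n_chroms, chrom_length, gc,
                            seed = derive_seed(seed, "genome"))
  cfg <- sv_sim_config(sv_counts, length_range = sv_length_range,
                       seed = derive_seed(seed, "svs"))
  truth <- generate_random_svs(cfg, genome)
  haps <- apply_svs(genome, truth)
  read_stats <- NULL
  if (coverage > 0) {
    rc <- if (is.null(read_config)) {
      read_sim_config(coverage = coverage, median_length = 8000L,
                      length_range = c(500L, 30000L),
                      seed = derive_seed(seed, "reads"))
    } else read_config
    sim <- simulate_reads(list(hap1 = haps$hap1, hap2 = haps$hap2),
                          profile, rc)
    tlen <- sim$truth$end - sim$truth$start + 1
    read_stats <- data.frame(
      n_reads = nrow(sim$truth),
      total_bases = sum(sim$truth$read_len),
      realized_coverage = sum(tlen) /
        mean(c(sum(nchar(haps$hap1)), sum(nchar(haps$hap2)))),
      median_length = stats::median(tlen),
      mean_identity = 1 - mean((sim$truth$n_sub + sim$truth$n_ins +
                                  sim$truth$n_del) / tlen))
  }
  benchmarks <- list()
  all_calls <- list()
  for (spec in pseudo_callers) {
    calls <- perturb_truth(truth, spec, genome)
    all_calls[[spec$name]] <- calls
    benchmarks[[spec$name]] <- benchmark_calls(calls, truth, bench)
  }
  merged_input <- do.call(rbind, all_calls)
  consensus <- combine_sv_calls(merged_input, combine)
  benchmarks$combined <- benchmark_calls(
    consensus[, c("caller", "chrom", "pos", "length", "sv_type", "genotype",
                  "support", "filter")],
    truth, bench)
  summary <- do.call(rbind, lapply(names(benchmarks), function(nm) {
    b <- benchmarks[[nm]]
    data.frame(call_set = nm, tp = b$tp, fp = b$fp, fn = b$fn,
               recall = b$recall, precision = b$precision,
               f_score = b$f_score, total_score = b$total_score,
               perfect = b$perfect_matches, stringsAsFactors = FALSE)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(summary, file.path(out_dir, "roundtrip_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(read_stats)) {
      write.table(read_stats, file.path(out_dir, "read_stats.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(truth = truth, read_stats = read_stats, benchmarks = benchmarks,
       summary = summary)
}

#' Default panel of three pseudo-callers for round-trip experiments
#'
#' @param seed master seed
#' @return list of [pseudo_caller_spec()]s
#' @export
default_pseudo_panel <- function(seed = 1L) {
  list(
    pseudo_caller_spec("pbsv", pos_jitter_sd = 20, len_jitter_frac = 0.02,
                       fn_rate = 0.10, fp_rate_per_mb = 5,
                       gt_error_rate = 0.05,
                       seed = derive_seed(seed, "pc-pbsv")),
    pseudo_caller_spec("cuteSV", pos_jitter_sd = 40, len_jitter_frac = 0.05,
                       fn_rate = 0.08, fp_rate_per_mb = 8,
                       gt_error_rate = 0.03,
                       seed = derive_seed(seed, "pc-cutesv")),
    pseudo_caller_spec("Sniffles", pos_jitter_sd = 60, len_jitter_frac = 0.08,
                       fn_rate = 0.12, fp_rate_per_mb = 12,
                       gt_error_rate = 0.08,
                       type_confusion = data.frame(from = "INS", to = "DUP",
                                                   prob = 0.2),
                       seed = derive_seed(seed, "pc-sniffles")))
}
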