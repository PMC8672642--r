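#' Benchmark configuration
#'
#' Defaults follow the evaluation scheme used throughout the package: a
#' candidate call matches a truth SV when the called position lies within
#' `pos_window` (1600 bp) of the truth position and, if the caller reported
#' a length, the length agrees within a 35% margin for truth SVs longer
#' than 300 bp and exactly for shorter ones (`short_len_margin` relaxes
#' that; see Details). Matching never depends on called type or genotype.
#' A matched call scores
#' `0.4 * max(0, 1 - |dpos|/pos_window) + 0.2 * max(0, 1 - |dlen|/(len_margin*truth_len))
#'  + 0.2 * [type correct] + 0.2 * [genotype correct]`.
#'
#' Calls are pre-filtered to FILTER PASS (or '.'/missing, which many callers
#' emit), length >= `min_length` bp (length-undetermined records are kept),
#' and >= `min_support` supporting reads (3 by default, 5 recommended at
#' depths of 30x and above; records without any support field are kept).
#'
#' @param pos_window maximum position difference for a match (bp)
#' @param len_margin fractional length tolerance for truth SVs longer than
#'   `len_margin_threshold`
#' @param len_margin_threshold truth length (bp) above which `len_margin`
#'   applies
#' @param short_len_margin fractional tolerance for truth SVs at or below
#'   the threshold; 0 demands an exact length match
#' @param min_length filtering floor on call length (bp)
#' @param min_support filtering floor on supporting reads
#' @param weights named numeric: pos, len, type, gt score weights
#' @param type_equiv optional data.frame (call_type, truth_type) of extra
#'   type pairs counted as correct (e.g. DUP vs INS)
#' @return list of class `benchmark_config`
#' @export
benchmark_config <- function(pos_window = 1600L, len_margin = 0.35,
                             len_margin_threshold = 300L,
                             short_len_margin = 0,
                             min_length = 50L, min_support = 3L,
                             weights = c(pos = 0.4, len = 0.2,
                                         type = 0.2, gt = 0.2),
                             type_equiv = NULL) {
  stopifnot(abs(sum(weights) - 1) < 1e-9,
            all(c("pos", "len", "type", "gt") %in% names(weights)))
  structure(list(pos_window = as.integer(pos_window),
                 len_margin = len_margin,
                 len_margin_threshold = as.integer(len_margin_threshold),
                 short_len_margin = short_len_margin,
                 min_length = as.integer(min_length),
                 min_support = as.integer(min_support),
                 weights = weights, type_equiv = type_equiv),
            class = "benchmark_config")
}

#' Parse a caller VCF into call records
#'
#' Tolerant of symbolic ALTs and of the support-field conventions of common
#' long-read SV callers: the number of supporting reads is taken from the
#' first available of the INFO keys SUPPORT, RE, DV, SU or the FORMAT field
#' DV. Length is |SVLEN|, else END-POS, else derived from REF/ALT, else 0
#' (undetermined, e.g. BND). The type comes from SVTYPE or a symbolic ALT;
#' sequence-resolved records fall back to DEL/INS by allele lengths.
#'
#' @param path VCF file
#' @param caller label recorded in the `caller` column
#' @return data.frame of call records: caller, chrom, pos, length, sv_type,
#'   genotype (het/hom/missing), support, filter
#' @export
read_caller_vcf <- function(path, caller = "caller") {
  v <- read_vcf_records(path)
  rec <- v$records
  n <- nrow(rec)
  if (!n) {
    return(data.frame(caller = character(0), chrom = character(0),
                      pos = integer(0), length = integer(0),
                      sv_type = character(0), genotype = character(0),
                      support = integer(0), filter = character(0),
                      stringsAsFactors = FALSE))
  }
  svtype <- info_field(rec$info, "SVTYPE")
  svlen <- suppressWarnings(as.numeric(info_field(rec$info, "SVLEN")))
  end <- suppressWarnings(as.integer(info_field(rec$info, "END")))
  symbolic <- grepl("^<.+>$", rec$alt)
  sym_type <- toupper(sub("^<([^:>]+).*>$", "\\1", rec$alt))
  type <- toupper(svtype)
  type[is.na(type) & symbolic] <- sym_type[is.na(type) & symbolic]
  bnd_alt <- grepl("[\\[\\]]", rec$alt)
  type[is.na(type) & bnd_alt] <- "BND"
  seqres <- is.na(type) & !symbolic & !bnd_alt
  type[seqres & nchar(rec$ref) > nchar(rec$alt)] <- "DEL"
  type[seqres & nchar(rec$ref) < nchar(rec$alt)] <- "INS"
  type[is.na(type)] <- "UNKNOWN"

  len <- abs(svlen)
  len[is.na(len) & !is.na(end)] <- (end - rec$pos)[is.na(len) & !is.na(end)]
  fix <- is.na(len) & seqres
  len[fix] <- abs(nchar(rec$ref) - nchar(rec$alt))[fix]
  len[is.na(len) | len < 0] <- 0
  len[type == "BND"] <- 0

  ## anchor-base normalization: sequence-resolved indel records place POS on
  ## the base before the event; report the first affected base instead so
  ## that positions are comparable with symbolic and truth records
  pos <- rec$pos
  anchored <- !symbolic & !bnd_alt & nchar(rec$ref) > 1L &
    substr(rec$ref, 1L, 1L) == substr(rec$alt, 1L, 1L)
  pos[anchored] <- pos[anchored] + 1L

  sup <- rep(NA_character_, n)
  for (key in c("SUPPORT", "RE", "DV", "SU")) {
    cand <- info_field(rec$info, key)
    sup[is.na(sup)] <- cand[is.na(sup)]
  }
  fmt_dv <- format_field(rec$format, rec$sample, "DV")
  sup[is.na(sup)] <- fmt_dv[is.na(sup)]
  support <- suppressWarnings(as.integer(sub(",.*", "", sup)))

  gt <- format_field(rec$format, rec$sample, "GT")
  genotype <- rep("missing", n)
  gt_clean <- gsub("\\|", "/", ifelse(is.na(gt), "", gt))
  genotype[gt_clean %in% c("0/1", "1/0")] <- "het"
  genotype[gt_clean %in% c("1/1", "1")] <- "hom"

  data.frame(caller = caller, chrom = rec$chrom, pos = pos,
             length = as.integer(round(len)), sv_type = type,
             genotype = genotype, support = support, filter = rec$filter,
             stringsAsFactors = FALSE)
}

#' Filter call records before benchmarking
#'
#' @param calls data.frame from [read_caller_vcf()]
#' @param config a [benchmark_config()]
#' @return the retained rows
#' @export
filter_calls <- function(calls, config = benchmark_config()) {
  pass <- calls$filter %in% c("PASS", ".", "") | is.na(calls$filter)
  len_ok <- calls$length >= config$min_length | calls$length == 0
  sup_ok <- is.na(calls$support) | calls$support >= config$min_support
  calls[pass & len_ok & sup_ok, , drop = FALSE]
}

## TRUE where call length and truth length are compatible under the margin
## rules; length-undetermined calls (0/NA) are compatible with anything.
length_compatible <- function(call_len, truth_len, config) {
  undet <- is.na(call_len) | call_len == 0
  dlen <- abs(call_len - truth_len)
  margin <- ifelse(truth_len > config$len_margin_threshold,
                   config$len_margin, config$short_len_margin)
  undet | dlen <= margin * truth_len
}

type_correct <- function(call_type, truth_type, config) {
  ok <- call_type == truth_type
  if (!is.null(config$type_equiv)) {
    for (i in seq_len(nrow(config$type_equiv))) {
      ok <- ok | (call_type == config$type_equiv$call_type[i] &
                    truth_type == config$type_equiv$truth_type[i])
    }
  }
  ok
}

gt_correct <- function(call_gt, truth_gt) {
  (call_gt == "hom" & truth_gt == "HOM") |
    (call_gt == "het" & truth_gt %in% c("HET_H1", "HET_H2"))
}

#' Match calls one-to-one against a truth set
#'
#' Candidate pairs lie on the same chromosome within `pos_window` bp and
#' satisfy the length-margin rule; type and genotype never gate matching.
#' Assignment is greedy by smallest |dpos|, ties broken by smaller |dlen|
#' then input order, and one-to-one: every unmatched call is a false
#' positive, every unmatched truth SV a false negative.
#'
#' @param calls filtered call records
#' @param truth SV event data.frame ([sv_events()])
#' @param config a [benchmark_config()]
#' @return list with `matches` (one row per true positive: call/truth
#'   indices, deltas, correctness flags, sub-scores and `score`), `fp`
#'   (indices into `calls`) and `fn` (indices into `truth`)
#' @export
match_calls <- function(calls, truth, config = benchmark_config()) {
  if (!nrow(truth)) stop("empty truth set")
  cand <- NULL
  if (nrow(calls)) {
    qr <- IRanges::IRanges(start = calls$pos, width = 1L)
    sr <- IRanges::IRanges(start = truth$start, width = 1L)
    hits <- IRanges::findOverlaps(qr, sr, maxgap = config$pos_window)
    ci <- S4Vectors::queryHits(hits)
    ti <- S4Vectors::subjectHits(hits)
    same_chrom <- calls$chrom[ci] == truth$chrom[ti]
    ci <- ci[same_chrom]; ti <- ti[same_chrom]
    ok <- length_compatible(calls$length[ci], truth$length[ti], config)
    cand <- data.frame(ci = ci[ok], ti = ti[ok])
  }
  m_ci <- integer(0); m_ti <- integer(0)
  if (!is.null(cand) && nrow(cand)) {
    dpos <- abs(calls$pos[cand$ci] - truth$start[cand$ti])
    dlen <- abs(calls$length[cand$ci] - truth$length[cand$ti])
    ord <- order(dpos, dlen, cand$ci)
    call_free <- rep(TRUE, nrow(calls))
    truth_free <- rep(TRUE, nrow(truth))
    for (j in ord) {
      a <- cand$ci[j]; b <- cand$ti[j]
      if (call_free[a] && truth_free[b]) {
        call_free[a] <- FALSE
        truth_free[b] <- FALSE
        m_ci <- c(m_ci, a)
        m_ti <- c(m_ti, b)
      }
    }
  }
  matches <- score_matches(calls, truth, m_ci, m_ti, config)
  list(matches = matches,
       fp = setdiff(seq_len(nrow(calls)), m_ci),
       fn = setdiff(seq_len(nrow(truth)), m_ti))
}

## Score table for matched pairs.
score_matches <- function(calls, truth, ci, ti, config) {
  w <- config$weights
  dpos <- abs(calls$pos[ci] - truth$start[ti])
  undet <- is.na(calls$length[ci]) | calls$length[ci] == 0
  dlen <- abs(calls$length[ci] - truth$length[ti])
  pos_score <- w[["pos"]] * pmax(0, 1 - dpos / config$pos_window)
  len_score <- ifelse(undet, 0,
                      w[["len"]] * pmax(0, 1 - dlen /
                                          (config$len_margin * truth$length[ti])))
  ty <- type_correct(calls$sv_type[ci], truth$sv_type[ti], config)
  gt <- gt_correct(calls$genotype[ci], truth$genotype[ti])
  data.frame(call = ci, truth = ti,
             delta_pos = dpos, delta_len = ifelse(undet, NA_integer_, dlen),
             type_correct = ty, gt_correct = gt,
             pos_score = pos_score, len_score = len_score,
             type_score = w[["type"]] * ty, gt_score = w[["gt"]] * gt,
             score = pos_score + len_score + w[["type"]] * ty +
               w[["gt"]] * gt,
             stringsAsFactors = FALSE)
}

#' Score a single matched call
#'
#' @param match one row of the `matches` table from [match_calls()]
#' @param config a [benchmark_config()]
#' @return numeric score in [0, 1]
#' @export
score_call <- function(match, config = benchmark_config()) {
  if (is.null(match) || !nrow(match) || is.na(match$truth[1])) {
    stop("score_call requires a matched call (false positives score nothing)")
  }
  match$score[1]
}

#' Summarize a benchmark run
#'
#' @param matched output of [match_calls()]
#' @param truth the truth SV event data.frame
#' @param calls the filtered call records
#' @param config a [benchmark_config()]
#' @return list of class `benchmark_report`: recall, precision, f_score,
#'   total_score (percent), counts, per-type recall/precision table,
#'   per-parameter mean sub-scores (0-1 scale) and the perfect-match count
#' @export
compute_metrics <- function(matched, truth, calls,
                            config = benchmark_config()) {
  m <- matched$matches
  tp <- nrow(m)
  n_fp <- length(matched$fp)
  n_fn <- length(matched$fn)
  stopifnot(tp + n_fn == nrow(truth), tp + n_fp == nrow(calls))
  recall <- if (tp + n_fn > 0) tp / (tp + n_fn) else 0
  precision <- if (tp + n_fp > 0) tp / (tp + n_fp) else 0
  f_score <- if (precision + recall > 0) {
    2 * ((precision * recall) / (precision + recall))
  } else 0
  total_score <- max(0, 100 * (sum(m$score) - n_fp) / nrow(truth))
  w <- config$weights
  per_param <- if (tp > 0) {
    c(position = mean(m$pos_score) / w[["pos"]],
      length = mean(m$len_score) / w[["len"]],
      type = mean(m$type_score) / w[["type"]],
      genotype = mean(m$gt_score) / w[["gt"]])
  } else {
    c(position = NA_real_, length = NA_real_, type = NA_real_,
      genotype = NA_real_)
  }
  types <- sort(unique(c(truth$sv_type, calls$sv_type)))
  per_type <- do.call(rbind, lapply(types, function(ty) {
    t_idx <- which(truth$sv_type == ty)
    c_idx <- which(calls$sv_type == ty)
    tp_t <- sum(m$truth %in% t_idx)
    tp_c <- sum(m$call %in% c_idx)
    data.frame(sv_type = ty, n_truth = length(t_idx), n_calls = length(c_idx),
               recall = if (length(t_idx)) tp_t / length(t_idx) else NA,
               precision = if (length(c_idx)) tp_c / length(c_idx) else NA,
               stringsAsFactors = FALSE)
  }))
  structure(list(tp = tp, fp = n_fp, fn = n_fn,
                 recall = recall, precision = precision, f_score = f_score,
                 total_score = total_score,
                 perfect_matches = sum(m$score == 1),
                 per_parameter = per_param, per_type = per_type),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("recall %.4f  precision %.4f  F %.4f  total score %.1f%%\n",
              x$recall, x$precision, x$f_score, x$total_score))
  cat(sprintf("perfect matches: %d\n", x$perfect_matches))
  cat("mean sub-scores: ",
      paste(sprintf("%s %.3f", names(x$per_parameter), x$per_parameter),
            collapse = "  "), "\n")
  invisible(x)
}

#' Benchmark a caller VCF (or call table) against a truth set
#'
#' Convenience wrapper: filter, match, score, summarize.
#'
#' @param calls call records or a VCF path
#' @param truth SV event data.frame or truth VCF/TSV path
#' @param config a [benchmark_config()]
#' @param caller label when `calls` is a path
#' @return a `benchmark_report` (see [compute_metrics()]); the filtered
#'   calls and match table are attached as attributes `calls` and `matched`
#' @export
benchmark_calls <- function(calls, truth, config = benchmark_config(),
                            caller = "caller") {
  if (is.character(calls)) calls <- read_caller_vcf(calls, caller)
  if (is.character(truth)) truth <- parse_sv_list(truth, toy = TRUE)
  kept <- filter_calls(calls, config)
  matched <- match_calls(kept, truth, config)
  rep <- compute_metrics(matched, truth, kept, config)
  attr(rep, "calls") <- kept
  attr(rep, "matched") <- matched
  rep
}

#' Write a benchmark report as TSV + text
#'
#' @param report a `benchmark_report`
#' @param dir output directory (created if needed)
#' @return paths, invisibly
#' @export
write_benchmark_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- data.frame(metric = c("tp", "fp", "fn", "recall", "precision",
                                "f_score", "total_score", "perfect_matches",
                                paste0("subscore_",
                                       names(report$per_parameter))),
                     value = c(report$tp, report$fp, report$fn, report$recall,
                               report$precision, report$f_score,
                               report$total_score, report$perfect_matches,
                               unname(report$per_parameter)))
  p1 <- file.path(dir, "summary.tsv")
  p2 <- file.path(dir, "per_type.tsv")
  p3 <- file.path(dir, "report.txt")
  write.table(summ, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$per_type, p2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  sink(p3); print(report); sink()
  invisible(c(p1, p2, p3))
}
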