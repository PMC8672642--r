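#' Configuration for long-read simulation
#'
#' Read lengths follow a log-normal law whose location parameter is solved
#' numerically so that the median of the truncated-to-`length_range`
#' distribution equals `median_length`. Coverage is either uniform
#' (`coverage`) or driven by a windowed depth profile, but not both.
#'
#' @param coverage target mean fold-coverage (ignored when `depth_profile`
#'   is supplied)
#' @param median_length target median read length (bp)
#' @param length_range `c(min, max)` read-length truncation bounds (bp)
#' @param sdlog log-scale spread of the read-length law
#' @param accuracy_override if set, the error profile is rescaled to this
#'   overall accuracy before simulation
#' @param depth_profile optional data.frame with columns
#'   `chrom, start, end, depth` of non-overlapping windows
#' @param seed integer seed; output is byte-identical for a fixed seed
#' @param circular wrap reads around the template end instead of clipping
#' @return list of class `read_sim_config`
#' @export
read_sim_config <- function(coverage = NULL, median_length = 8000L,
                            length_range = c(100L, 50000L), sdlog = 0.35,
                            accuracy_override = NULL, depth_profile = NULL,
                            seed = 1L, circular = FALSE) {
  if (is.null(coverage) == is.null(depth_profile)) {
    stop("supply exactly one of coverage or depth_profile")
  }
  stopifnot(length_range[1] <= median_length,
            median_length <= length_range[2])
  if (!is.null(depth_profile)) {
    stopifnot(all(c("chrom", "start", "end", "depth") %in%
                    names(depth_profile)),
              all(depth_profile$depth >= 0))
    for (ch in unique(depth_profile$chrom)) {
      w <- depth_profile[depth_profile$chrom == ch, ]
      w <- w[order(w$start), ]
      if (any(w$start[-1] <= w$end[-nrow(w)])) {
        stop("depth-profile windows overlap on ", ch)
      }
    }
  }
  meanlog <- solve_lnorm_meanlog(median_length, length_range, sdlog)
  structure(list(coverage = coverage, median_length = as.integer(median_length),
                 length_range = as.integer(length_range), sdlog = sdlog,
                 meanlog = meanlog, accuracy_override = accuracy_override,
                 depth_profile = depth_profile, seed = as.integer(seed),
                 circular = circular),
            class = "read_sim_config")
}

## meanlog such that the median of the [min,max]-truncated log-normal is the
## requested median length.
solve_lnorm_meanlog <- function(median_length, range, sdlog) {
  if (range[1] == range[2]) return(log(range[1]))
  trunc_median <- function(mu) {
    a <- plnorm(range[1], mu, sdlog)
    b <- plnorm(range[2], mu, sdlog)
    qlnorm(a + 0.5 * (b - a), mu, sdlog)
  }
  f <- function(mu) trunc_median(mu) - median_length
  uniroot(f, interval = log(c(range[1], range[2])), extendInt = "yes",
          tol = 1e-9)$root
}

#' Sample read lengths
#'
#' @param config a [read_sim_config()]
#' @param n number of draws
#' @return integer vector of lengths within the configured range
#' @export
sample_read_length <- function(config, n = 1L) {
  lo <- config$length_range[1]
  hi <- config$length_range[2]
  if (lo == hi) return(rep(lo, n))
  a <- plnorm(lo, config$meanlog, config$sdlog)
  b <- plnorm(hi, config$meanlog, config$sdlog)
  u <- runif(n, a, b)
  pmin(pmax(as.integer(round(qlnorm(u, config$meanlog, config$sdlog))), lo), hi)
}

#' Sample a read start position
#'
#' Uniform over the positions where the read fits the template, or, under a
#' depth profile, windows are chosen with probability proportional to
#' `depth * width` so the expected per-window coverage is proportional to
#' the requested depth. Zero-depth windows receive no read starts.
#'
#' @param template_length template length (bp)
#' @param read_length read length (bp)
#' @param depth_profile optional windows for one chromosome
#' @param n number of draws
#' @return integer vector of 1-based start positions
#' @export
sample_read_start <- function(template_length, read_length,
                              depth_profile = NULL, n = 1L) {
  lim <- template_length - read_length + 1L
  if (lim < 1L) stop("read longer than template")
  if (is.null(depth_profile)) {
    return(as.integer(ceiling(runif(n) * lim)))
  }
  w <- depth_profile
  wt <- w$depth * (pmin(w$end, lim) - w$start + 1)
  wt[pmin(w$end, lim) < w$start] <- 0
  if (all(wt == 0)) stop("depth profile has no positive-depth window")
  wi <- sample.int(nrow(w), n, replace = TRUE, prob = wt)
  lo <- w$start[wi]
  hi <- pmin(w$end[wi], lim)
  as.integer(lo + floor(runif(n) * (hi - lo + 1)))
}

#' Introduce context-specific sequencing errors into a template
#'
#' Walks the template: at each base with a full 3-mer context the profile's
#' context rates apply (the two terminal bases use the profile's mean
#' rates); a deletion removes a run drawn from the deletion-length
#' distribution, a substitution replaces the base according to the
#' context's target distribution, and with the insertion rate a run of
#' random bases (length from the insertion-length distribution) is inserted
#' after the base. Bases inside a deletion run generate no further events.
#'
#' @param template nucleotide string (>= 3 bp)
#' @param profile an [error_profile()]
#' @return list with `read` (corrupted sequence), and the ground-truth edit
#'   list: `sub_pos`, `sub_alt`, `ins_pos`, `ins_len`, `del_pos`, `del_len`
#'   (all in template coordinates)
#' @export
corrupt_sequence <- function(template, profile) {
  ints <- dna_to_int(template)
  n <- length(ints)
  stopifnot(n >= 3L)
  k <- kmer_index(ints)
  ctx <- profile$contexts
  sub_r <- ctx$sub_rate[k]
  ins_r <- ctx$ins_rate[k]
  del_r <- ctx$del_rate[k]
  sub_r[is.na(sub_r)] <- mean(ctx$sub_rate)
  ins_r[is.na(ins_r)] <- mean(ctx$ins_rate)
  del_r[is.na(del_r)] <- mean(ctx$del_rate)

  u <- runif(n)
  del_trig <- u < del_r
  sub_trig <- !del_trig & u < del_r + sub_r
  ins_trig <- runif(n) < ins_r

  ## resolve deletion runs left to right; triggers inside a run are void
  dcand <- which(del_trig)
  del_pos <- integer(0)
  del_len <- integer(0)
  if (length(dcand)) {
    lens <- sample.int(length(profile$del_len_dist), length(dcand),
                       replace = TRUE, prob = profile$del_len_dist)
    cur_end <- 0L
    keep <- logical(length(dcand))
    for (j in seq_along(dcand)) {
      if (dcand[j] > cur_end) {
        keep[j] <- TRUE
        cur_end <- dcand[j] + lens[j] - 1L
      }
    }
    del_pos <- dcand[keep]
    del_len <- pmin(lens[keep], n - del_pos + 1L)
  }
  deleted <- logical(n)
  for (j in seq_along(del_pos)) {
    deleted[del_pos[j]:(del_pos[j] + del_len[j] - 1L)] <- TRUE
  }
  emitted <- !deleted
  sub_idx <- which(sub_trig & emitted)
  ins_idx <- which(ins_trig & emitted)

  out_base <- ints[emitted]
  ## substitution targets per context
  sub_alt <- integer(length(sub_idx))
  if (length(sub_idx)) {
    kk <- k[sub_idx]
    r <- runif(length(sub_idx))
    tgt <- as.matrix(ctx[, c("sub_A", "sub_C", "sub_G", "sub_T")])
    has_ctx <- !is.na(kk)
    if (any(has_ctx)) {
      c1 <- tgt[kk[has_ctx], 1]
      c2 <- c1 + tgt[kk[has_ctx], 2]
      c3 <- c2 + tgt[kk[has_ctx], 3]
      ri <- r[has_ctx]
      sub_alt[has_ctx] <- 0L + (ri > c1) + (ri > c2) + (ri > c3)
    }
    if (any(!has_ctx)) {  # terminal bases: uniform over the 3 alternatives
      shift <- 1L + floor(r[!has_ctx] * 3) %% 3L
      sub_alt[!has_ctx] <- (ints[sub_idx[!has_ctx]] + shift) %% 4L
    }
    emap <- cumsum(emitted)  # template -> emitted index
    out_base[emap[sub_idx]] <- sub_alt
  }
  ins_len <- integer(0)
  ins_seqs <- integer(0)
  if (length(ins_idx)) {
    ins_len <- sample.int(length(profile$ins_len_dist), length(ins_idx),
                          replace = TRUE, prob = profile$ins_len_dist)
    ins_seqs <- sample_bases_int(sum(ins_len))
  }
  m <- length(out_base)
  if (length(ins_idx)) {
    emap <- cumsum(emitted)
    ins_by_emit <- integer(m)
    ins_by_emit[emap[ins_idx]] <- ins_len
    off_before <- cumsum(c(0L, ins_by_emit))[seq_len(m)]
    out <- integer(m + sum(ins_len))
    place <- seq_len(m) + off_before
    out[place] <- out_base
    out[-place] <- ins_seqs
  } else {
    out <- out_base
  }
  list(read = if (length(out)) int_to_dna(out) else "",
       sub_pos = sub_idx,
       sub_alt = if (length(sub_idx)) {
         strsplit(int_to_dna(sub_alt), "")[[1]]
       } else character(0),
       ins_pos = ins_idx, ins_len = as.integer(ins_len),
       del_pos = del_pos, del_len = as.integer(del_len))
}

#' Simulate long reads from haplotype sequences
#'
#' Reads are drawn until the summed template span reaches
#' `coverage * genome size` (or the depth-profile target). Each read picks a
#' haplotype with probability 1/2, a chromosome proportional to its length,
#' a length from the configured law, a start position (uniform or
#' depth-profile driven) and a strand 50/50; the template is corrupted with
#' the error profile and minus-strand reads are reverse-complemented on
#' output. Output is byte-identical for a fixed seed.
#'
#' @param haplotypes a named character vector, or a list of one or two of
#'   them (e.g. `list(hap1 = ..., hap2 = ...)`)
#' @param profile an [error_profile()]
#' @param config a [read_sim_config()]
#' @param out_prefix if non-NULL, writes `<prefix>.fastq` and
#'   `<prefix>_truth.tsv`
#' @return invisible list with `reads` (named character vector of read
#'   sequences), `truth` (per-read data.frame: read_id, hap, chrom, start,
#'   end, strand, n_sub, n_ins, n_del), `records` (list of [aln_record()]s
#'   in template coordinates, for profile retraining) and `paths`
#' @export
simulate_reads <- function(haplotypes, profile, config, out_prefix = NULL) {
  if (!is.list(haplotypes)) haplotypes <- list(hap1 = haplotypes)
  haplotypes <- lapply(haplotypes, as_seq_set)
  if (is.null(names(haplotypes))) {
    names(haplotypes) <- paste0("hap", seq_along(haplotypes))
  }
  if (!is.null(config$accuracy_override)) {
    profile <- scale_profile(profile, config$accuracy_override)
  }
  genome_size <- mean(vapply(haplotypes, function(h) sum(nchar(h)),
                             numeric(1)))
  dp <- config$depth_profile
  target <- if (is.null(dp)) {
    config$coverage * genome_size
  } else {
    sum(dp$depth * (dp$end - dp$start + 1))
  }
  acc <- profile_accuracy(profile)
  qchar <- rawToChar(as.raw(33L + max(1L, min(93L, round(
    -10 * log10(max(1 - acc, 1e-9)))))))

  reads <- character(0)
  records <- list()
  tr <- list(read_id = character(0), hap = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             n_sub = integer(0), n_ins = integer(0), n_del = integer(0),
             read_len = integer(0))
  total <- 0
  i <- 0L
  with_seed(derive_seed(config$seed, "read-sim"), {
    while (total < target) {
      i <- i + 1L
      hap_i <- if (length(haplotypes) > 1L) {
        sample.int(length(haplotypes), 1L)
      } else 1L
      hap <- haplotypes[[hap_i]]
      lens <- nchar(hap)
      ch <- names(hap)[sample.int(length(hap), 1L, prob = lens)]
      L <- min(sample_read_length(config, 1L), lens[[ch]])
      start <- if (is.null(dp)) {
        sample_read_start(lens[[ch]], L)
      } else {
        dpc <- dp[dp$chrom == ch, , drop = FALSE]
        if (!nrow(dpc)) next
        sample_read_start(lens[[ch]], L, depth_profile = dpc)
      }
      template <- substr(hap[[ch]], start, start + L - 1L)
      strand <- if (runif(1) < 0.5) "+" else "-"
      cor <- corrupt_sequence(template, profile)
      read_seq <- if (strand == "-") revcomp_chr(cor$read) else cor$read
      rid <- sprintf("read%06d", i)
      reads[[rid]] <- read_seq
      ## truth edits are recorded in template (reference) orientation
      records[[length(records) + 1L]] <- aln_record(
        ch, start, start + L - 1L,
        sub_pos = cor$sub_pos + start - 1L, sub_alt = cor$sub_alt,
        ins_pos = cor$ins_pos + start - 1L, ins_len = cor$ins_len,
        del_pos = cor$del_pos + start - 1L, del_len = cor$del_len)
      j <- length(tr$read_id) + 1L
      tr$read_id[j] <- rid
      tr$hap[j] <- names(haplotypes)[hap_i]
      tr$chrom[j] <- ch
      tr$start[j] <- start
      tr$end[j] <- start + L - 1L
      tr$strand[j] <- strand
      tr$n_sub[j] <- length(cor$sub_pos)
      tr$n_ins[j] <- sum(cor$ins_len)
      tr$n_del[j] <- sum(cor$del_len)
      tr$read_len[j] <- nchar(read_seq)
      total <- total + L
    }
  })
  truth <- as.data.frame(tr, stringsAsFactors = FALSE)
  paths <- NULL
  if (!is.null(out_prefix)) {
    fq <- paste0(out_prefix, ".fastq")
    con <- file(fq, "w")
    for (rid in names(reads)) {
      writeLines(c(paste0("@", rid), reads[[rid]], "+",
                   strrep(qchar, nchar(reads[[rid]]))), con)
    }
    close(con)
    tt <- paste0(out_prefix, "_truth.tsv")
    write.table(truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(fastq = fq, truth = tt)
  }
  invisible(list(reads = reads, truth = truth, records = records,
                 paths = paths))
}

#' Read a depth-profile TSV (chrom, start, end, depth)
#'
#' Compatible with windowed summaries of `samtools depth` output.
#'
#' @param path TSV file with header
#' @return data.frame with columns chrom, start, end, depth
#' @export
read_depth_profile <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(d)))
  d
}
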