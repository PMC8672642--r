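#' Configuration for multi-caller consensus merging
#'
#' Consensus rules: a clustered SV is emitted when at least `min_callers`
#' distinct callers support it (by default 2 when 2-5 callers are combined
#' and 3 when 6 are), or when it matches a rescue rule admitting a
#' low-false-positive single-caller category (defaults: homozygous calls
#' from SVIM, heterozygous insertions and deletions from Sniffles). Position
#' and length of the emitted record are copied from the highest-priority
#' caller present under the position/length ranking; genotype under the
#' genotype ranking; the SV type comes from the highest-priority caller with
#' a resolved (non-BND) type. Records below `min_alt_coverage` supporting
#' reads are dropped at load time. One of cuteSV, Sniffles or pbsv is
#' expected among the inputs (a warning, not an error, if absent).
#'
#' @param priority_pos_len caller ranking used for position and length
#' @param priority_gt caller ranking used for genotype
#' @param min_callers distinct-caller confirmation threshold; `NULL`
#'   resolves from the number of inputs (2 for 2-5, 3 for 6+)
#' @param min_alt_coverage minimum supporting reads per input record
#' @param rescue_rules data.frame (caller, sv_type, genotype); `"*"`
#'   matches anything. Ignored when `no_singletons = TRUE`
#' @param anchor_callers callers of which at least one should be present
#' @param merge_window clustering window (bp); lengths must additionally be
#'   compatible under the benchmark margin rules
#' @param no_singletons drop all rescue rules
#' @param bench benchmark_config supplying the length-compatibility margins
#' @return list of class `combine_config`
#' @export
combine_config <- function(priority_pos_len = c("pbsv", "cuteSV", "Sniffles",
                                                "SVIM", "NanoVar", "NanoSV"),
                           priority_gt = c("cuteSV", "pbsv", "Sniffles",
                                           "SVIM", "NanoVar", "NanoSV"),
                           min_callers = NULL,
                           min_alt_coverage = 3L,
                           rescue_rules = data.frame(
                             caller = c("SVIM", "Sniffles", "Sniffles"),
                             sv_type = c("*", "INS", "DEL"),
                             genotype = c("hom", "het", "het"),
                             stringsAsFactors = FALSE),
                           anchor_callers = c("cuteSV", "Sniffles", "pbsv"),
                           merge_window = 1600L,
                           no_singletons = FALSE,
                           bench = benchmark_config()) {
  if (!is.null(min_callers)) stopifnot(min_callers >= 1L)
  structure(list(priority_pos_len = priority_pos_len,
                 priority_gt = priority_gt,
                 min_callers = min_callers,
                 min_alt_coverage = as.integer(min_alt_coverage),
                 rescue_rules = rescue_rules,
                 anchor_callers = anchor_callers,
                 merge_window = as.integer(merge_window),
                 no_singletons = no_singletons,
                 bench = bench),
            class = "combine_config")
}

#' Resolve the confirmation threshold for a number of input callers
#'
#' @param n_inputs number of caller VCFs combined
#' @param config a [combine_config()]
#' @return integer threshold (2 for 2-5 inputs, 3 for 6 or more, unless
#'   overridden in the config)
#' @export
resolve_min_callers <- function(n_inputs, config = combine_config()) {
  if (!is.null(config$min_callers)) return(as.integer(config$min_callers))
  if (n_inputs >= 6L) 3L else 2L
}

#' Load caller VCFs for combining
#'
#' @param paths named character vector `c(cuteSV = "a.vcf", pbsv = "b.vcf")`;
#'   names are the caller labels
#' @param config a [combine_config()]
#' @return single data.frame of call records tagged by caller, with records
#'   below `min_alt_coverage` support removed
#' @export
load_caller_vcfs <- function(paths, config = combine_config()) {
  if (length(paths) < 2L) stop("combining needs at least 2 caller VCFs")
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop("caller VCF paths must be named by caller label")
  }
  if (!any(names(paths) %in% config$anchor_callers)) {
    warning("none of ", paste(config$anchor_callers, collapse = "/"),
            " among the inputs; combining is possible but not recommended")
  }
  calls <- do.call(rbind, lapply(names(paths), function(lab) {
    read_caller_vcf(paths[[lab]], caller = lab)
  }))
  keep <- is.na(calls$support) | calls$support >= config$min_alt_coverage
  calls <- calls[keep, , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Cluster calls from different callers that describe the same SV
#'
#' Single-linkage within a chromosome: calls whose positions lie within
#' `merge_window` bp of a group member and whose lengths are mutually
#' compatible (same margin rules as benchmark matching, evaluated against
#' the group's seed call) share a group. A group holds at most one call per
#' caller; among several candidates from one caller the nearest wins and
#' the other starts its own group.
#'
#' @param calls loaded call records
#' @param config a [combine_config()]
#' @return integer vector of group ids, parallel to `calls` rows
#' @export
cluster_calls <- function(calls, config = combine_config()) {
  n <- nrow(calls)
  group <- integer(n)
  if (!n) return(group)
  next_id <- 0L
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    idx <- idx[order(calls$pos[idx])]
    seeds <- list()  # open groups: id, seed pos/len, member row indices
    new_group <- function(i) {
      next_id <<- next_id + 1L
      group[i] <<- next_id
      seeds[[length(seeds) + 1L]] <<- list(id = next_id, pos = calls$pos[i],
                                           len = calls$length[i],
                                           members = i)
    }
    for (i in idx) {
      best <- 0L
      best_d <- Inf
      for (gi in seq_along(seeds)) {
        g <- seeds[[gi]]
        d <- abs(calls$pos[i] - g$pos)
        if (d > config$merge_window) next
        if (!length_compatible_pair(calls$length[i], g$len, config$bench)) next
        if (d < best_d) { best <- gi; best_d <- d }
      }
      if (best > 0L) {
        g <- seeds[[best]]
        dup <- g$members[calls$caller[g$members] == calls$caller[i]]
        if (length(dup)) {
          ## one call per caller per group: the nearest to the seed wins
          if (best_d < abs(calls$pos[dup[1]] - g$pos)) {
            seeds[[best]]$members <- c(setdiff(g$members, dup[1]), i)
            group[i] <- g$id
            new_group(dup[1])
          } else {
            new_group(i)
          }
        } else {
          group[i] <- g$id
          seeds[[best]]$members <- c(g$members, i)
        }
      } else {
        new_group(i)
      }
      ## drop groups the position-sorted sweep has moved past
      seeds <- Filter(function(g) {
        calls$pos[i] - g$pos <= config$merge_window
      }, seeds)
    }
  }
  group
}

## Symmetric pairwise length compatibility used for clustering: the margin
## is taken on the larger of the two lengths.
length_compatible_pair <- function(l1, l2, bench) {
  if (is.na(l1) || l1 == 0 || is.na(l2) || l2 == 0) return(TRUE)
  big <- max(l1, l2)
  margin <- if (big > bench$len_margin_threshold) bench$len_margin else
    bench$short_len_margin
  abs(l1 - l2) <= margin * big
}

## Rank of each caller under a priority vector; unranked callers follow the
## ranked ones in input order.
caller_rank <- function(callers, priority) {
  r <- match(callers, priority)
  r[is.na(r)] <- length(priority) + seq_len(sum(is.na(r)))
  r
}

#' Resolve one cluster of calls into a consensus record (or drop it)
#'
#' @param group data.frame of call records from one cluster
#' @param min_callers resolved confirmation threshold
#' @param config a [combine_config()]
#' @return one-row consensus data.frame, or NULL when the group is neither
#'   confirmed by enough callers nor rescued
#' @export
resolve_group <- function(group, min_callers, config = combine_config()) {
  n_callers <- length(unique(group$caller))
  rescued <- FALSE
  if (n_callers < min_callers) {
    if (!config$no_singletons && nrow(config$rescue_rules)) {
      rr <- config$rescue_rules
      for (i in seq_len(nrow(rr))) {
        hit <- group$caller == rr$caller[i] &
          (rr$sv_type[i] == "*" | group$sv_type == rr$sv_type[i]) &
          (rr$genotype[i] == "*" | group$genotype == rr$genotype[i])
        if (any(hit)) { rescued <- TRUE; break }
      }
    }
    if (!rescued) return(NULL)
  }
  rk_pos <- caller_rank(group$caller, config$priority_pos_len)
  lead <- which.min(rk_pos)
  typed <- which(!group$sv_type %in% c("BND", "UNKNOWN"))
  ty <- if (length(typed)) {
    group$sv_type[typed[which.min(rk_pos[typed])]]
  } else "BND"
  rk_gt <- caller_rank(group$caller, config$priority_gt)
  gt_known <- which(group$genotype != "missing")
  gt <- if (length(gt_known)) {
    group$genotype[gt_known[which.min(rk_gt[gt_known])]]
  } else "missing"
  data.frame(caller = "combined", chrom = group$chrom[lead],
             pos = group$pos[lead], length = group$length[lead],
             sv_type = ty, genotype = gt,
             support = suppressWarnings(max(group$support, na.rm = TRUE)),
             filter = "PASS",
             n_callers = n_callers,
             callers = paste(sort(unique(group$caller)), collapse = ","),
             rescued = rescued,
             stringsAsFactors = FALSE)
}

#' Combine caller VCFs into a consensus call set
#'
#' @param paths named character vector of caller VCFs (see
#'   [load_caller_vcfs()]), or an already-loaded call data.frame
#' @param config a [combine_config()]
#' @param out optional path; when given, the consensus is written as a
#'   sorted VCF 4.2 with symbolic ALTs
#' @return consensus call data.frame (one row per emitted SV)
#' @export
combine_sv_calls <- function(paths, config = combine_config(), out = NULL) {
  if (is.data.frame(paths)) {
    calls <- paths
    n_inputs <- length(unique(calls$caller))
    if (n_inputs < 2L) stop("combining needs at least 2 callers")
  } else {
    n_inputs <- length(paths)
    calls <- load_caller_vcfs(paths, config)
  }
  min_callers <- resolve_min_callers(n_inputs, config)
  group <- cluster_calls(calls, config)
  pieces <- lapply(split(seq_len(nrow(calls)), group), function(ix) {
    resolve_group(calls[ix, , drop = FALSE], min_callers, config)
  })
  pieces <- Filter(Negate(is.null), pieces)
  res <- if (length(pieces)) {
    do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  } else NULL
  if (is.null(res)) {
    res <- data.frame(caller = character(0), chrom = character(0),
                      pos = integer(0), length = integer(0),
                      sv_type = character(0), genotype = character(0),
                      support = integer(0), filter = character(0),
                      n_callers = integer(0), callers = character(0),
                      rescued = logical(0), stringsAsFactors = FALSE)
  } else {
    res <- res[order(res$chrom, res$pos), , drop = FALSE]
    rownames(res) <- NULL
  }
  if (!is.null(out)) write_combined_vcf(res, out)
  res
}

#' Write a consensus call set as VCF 4.2
#'
#' @param consensus data.frame from [combine_sv_calls()]
#' @param path output path
#' @return the path, invisibly
#' @export
write_combined_vcf <- function(consensus, path) {
  extra <- c(
    '##INFO=<ID=SUPP_CALLERS,Number=1,Type=String,Description="Callers supporting the SV">',
    '##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description="Supporting reads (max over callers)">',
    '##INFO=<ID=RESCUED,Number=0,Type=Flag,Description="Admitted by a single-caller rescue rule">')
  n <- nrow(consensus)
  gt <- ifelse(consensus$genotype == "hom", "1/1",
               ifelse(consensus$genotype == "het", "0/1", "./."))
  info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d;SUPP_CALLERS=%s",
                  consensus$sv_type, consensus$length,
                  consensus$pos + pmax(consensus$length - 1L, 0L) *
                    (consensus$sv_type != "INS"),
                  consensus$callers)
  has_sup <- !is.na(consensus$support) & is.finite(consensus$support)
  info[has_sup] <- paste0(info[has_sup], ";SUPPORT=",
                          consensus$support[has_sup])
  info[consensus$rescued] <- paste0(info[consensus$rescued], ";RESCUED")
  rec <- data.frame(chrom = consensus$chrom, pos = consensus$pos,
                    id = sprintf("combi%05d", seq_len(n)),
                    ref = rep("N", n),
                    alt = sprintf("<%s>", consensus$sv_type),
                    qual = rep(".", n), filter = rep("PASS", n),
                    info = info, format = rep("GT", n), sample = gt,
                    stringsAsFactors = FALSE)
  write_vcf_lines(vcf_header(NULL, extra, sample = "COMBINED",
                             source = "svforge-combine"), rec, path)
}
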