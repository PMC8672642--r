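#' Construct a 3-mer context-specific sequencing error profile
#'
#' A profile stores, for each of the 64 trinucleotide contexts (the error
#' rates refer to the middle base), the per-base substitution, insertion and
#' deletion rates, the distribution of the substituted-to base, and global
#' insertion/deletion length distributions. The overall accuracy is never
#' stored; it is recomputed from the rates (see [profile_accuracy()]).
#'
#' @param contexts data.frame with 64 rows and columns `kmer`, `sub_rate`,
#'   `ins_rate`, `del_rate`, `sub_A`, `sub_C`, `sub_G`, `sub_T` (substitution
#'   target distribution; the entry of the reference base itself must be 0)
#' @param ins_len_dist numeric vector of insertion-length probabilities
#'   (index = length in bp), summing to 1
#' @param del_len_dist numeric vector of deletion-length probabilities,
#'   summing to 1
#' @param name profile label
#' @return object of class `error_profile`
#' @export
error_profile <- function(contexts, ins_len_dist = 1, del_len_dist = 1,
                          name = "custom") {
  kmers <- all_kmers3()
  stopifnot(is.data.frame(contexts))
  if (!setequal(contexts$kmer, kmers)) {
    miss <- setdiff(kmers, contexts$kmer)
    stop("contexts must cover all 64 3-mers; missing: ",
         paste(head(miss, 5), collapse = ", "))
  }
  contexts <- contexts[match(kmers, contexts$kmer), ]
  rownames(contexts) <- NULL
  rates <- c(contexts$sub_rate, contexts$ins_rate, contexts$del_rate)
  if (any(is.na(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("context rates must lie in [0, 1]")
  }
  if (any(contexts$sub_rate + contexts$del_rate > 1 + 1e-9)) {
    stop("sub_rate + del_rate must be <= 1 in every context")
  }
  tgt <- as.matrix(contexts[, c("sub_A", "sub_C", "sub_G", "sub_T")])
  mid <- substr(contexts$kmer, 2, 2)
  self <- tgt[cbind(seq_len(64), match(mid, BASES))]
  if (any(self != 0)) stop("sub target of the reference base itself must be 0")
  has_sub <- contexts$sub_rate > 0
  if (any(abs(rowSums(tgt[has_sub, , drop = FALSE]) - 1) > 1e-9)) {
    stop("sub target distributions must sum to 1")
  }
  norm_dist <- function(d, what) {
    d <- as.numeric(d)
    if (any(d < 0)) stop(what, " distribution has negative mass")
    if (sum(d) == 0) d <- c(1, rep(0, length(d) - 1))
    if (abs(sum(d) - 1) > 1e-9) stop(what, " distribution must sum to 1")
    d
  }
  structure(list(name = name, contexts = contexts,
                 ins_len_dist = norm_dist(ins_len_dist, "insertion length"),
                 del_len_dist = norm_dist(del_len_dist, "deletion length")),
            class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf("error_profile '%s': accuracy %.4f\n", x$name,
              profile_accuracy(x)))
  cat(sprintf("  mean rates: sub %.4g  ins %.4g  del %.4g\n",
              mean(x$contexts$sub_rate), mean(x$contexts$ins_rate),
              mean(x$contexts$del_rate)))
  invisible(x)
}

#' Overall accuracy of an error profile
#'
#' One minus the expected number of erroneous bases per template base on a
#' genome in which every 3-mer context is equally frequent: substitutions
#' count 1 error, indel events count their expected length.
#'
#' @param profile an [error_profile()]
#' @return accuracy in (0, 1]
#' @export
profile_accuracy <- function(profile) {
  e_ins <- sum(seq_along(profile$ins_len_dist) * profile$ins_len_dist)
  e_del <- sum(seq_along(profile$del_len_dist) * profile$del_len_dist)
  err <- mean(profile$contexts$sub_rate +
              profile$contexts$ins_rate * e_ins +
              profile$contexts$del_rate * e_del)
  1 - err
}

#' Rescale an error profile to a target overall accuracy
#'
#' All 64x3 context rates are multiplied by the single factor
#' `(1 - target) / (1 - current)`, preserving the relative differences
#' between contexts and between error kinds. Rates that would exceed the
#' `sub_rate + del_rate <= 1` boundary are clipped with a warning.
#'
#' @param profile an [error_profile()]
#' @param target_accuracy desired overall accuracy in (0, 1]
#' @return rescaled `error_profile`
#' @export
scale_profile <- function(profile, target_accuracy) {
  stopifnot(target_accuracy > 0, target_accuracy <= 1)
  cur <- profile_accuracy(profile)
  if (cur >= 1 && target_accuracy < 1) {
    stop("cannot scale an error-free profile to accuracy < 1")
  }
  factor <- if (target_accuracy == 1) 0 else (1 - target_accuracy) / (1 - cur)
  ctx <- profile$contexts
  for (col in c("sub_rate", "ins_rate", "del_rate")) {
    ctx[[col]] <- ctx[[col]] * factor
  }
  over <- ctx$sub_rate + ctx$del_rate > 1
  if (any(over)) {
    warning(sum(over), " context(s) clipped at the sub+del <= 1 boundary")
    tot <- ctx$sub_rate[over] + ctx$del_rate[over]
    ctx$sub_rate[over] <- ctx$sub_rate[over] / tot
    ctx$del_rate[over] <- ctx$del_rate[over] / tot
  }
  ctx$ins_rate <- pmin(ctx$ins_rate, 1)
  out <- profile
  out$contexts <- ctx
  got <- profile_accuracy(out)
  if (abs(got - target_accuracy) > 1e-6) {
    stop(sprintf(paste0("target accuracy %.4f unreachable (achieved %.4f ",
                        "after clipping)"), target_accuracy, got))
  }
  out
}

#' Build a uniform error profile
#'
#' Convenience constructor giving every context the same substitution,
#' insertion and deletion rates, uniform substitution targets and geometric
#' length distributions truncated at `l_max`.
#'
#' @param sub_rate,ins_rate,del_rate per-base event rates
#' @param l_max maximum indel length carried by the length distributions
#' @param geom_p success parameter of the truncated geometric length law
#' @param name profile label
#' @return an [error_profile()]
#' @export
uniform_error_profile <- function(sub_rate = 0.05, ins_rate = 0.02,
                                  del_rate = 0.03, l_max = 10,
                                  geom_p = 0.7, name = "uniform") {
  kmers <- all_kmers3()
  mid <- substr(kmers, 2, 2)
  tgt <- matrix(1 / 3, nrow = 64, ncol = 4,
                dimnames = list(NULL, paste0("sub_", BASES)))
  tgt[cbind(seq_len(64), match(mid, BASES))] <- 0
  ctx <- data.frame(kmer = kmers, sub_rate = sub_rate, ins_rate = ins_rate,
                    del_rate = del_rate, stringsAsFactors = FALSE)
  ctx <- cbind(ctx, as.data.frame(tgt))
  len <- geom_p * (1 - geom_p)^(seq_len(l_max) - 1)
  len <- len / sum(len)
  error_profile(ctx, ins_len_dist = len, del_len_dist = len, name = name)
}

#' Save an error profile as plain text
#'
#' Sectioned key-value format: `[meta]` (name), `[contexts]` (64 lines of
#' kmer, sub/ins/del rates and the 4 substitution-target probabilities),
#' `[ins_lengths]` and `[del_lengths]` (length, probability). Loading a
#' saved profile reproduces it to within 1e-9.
#'
#' @param profile an [error_profile()]
#' @param path output path
#' @return the path, invisibly
#' @export
save_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# svforge 3-mer error profile", "[meta]",
               paste0("name=", profile$name)), con)
  writeLines("[contexts]", con)
  ctx <- profile$contexts
  writeLines(sprintf("%s\t%.12g\t%.12g\t%.12g\t%.12g\t%.12g\t%.12g\t%.12g",
                     ctx$kmer, ctx$sub_rate, ctx$ins_rate, ctx$del_rate,
                     ctx$sub_A, ctx$sub_C, ctx$sub_G, ctx$sub_T), con)
  writeLines("[ins_lengths]", con)
  writeLines(sprintf("%d\t%.12g", seq_along(profile$ins_len_dist),
                     profile$ins_len_dist), con)
  writeLines("[del_lengths]", con)
  writeLines(sprintf("%d\t%.12g", seq_along(profile$del_len_dist),
                     profile$del_len_dist), con)
  invisible(path)
}

#' Load an error profile saved by [save_profile()]
#'
#' @param path profile file
#' @return an [error_profile()]
#' @export
load_profile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sec <- cumsum(grepl("^\\[.*\\]$", lines))
  names <- lines[grepl("^\\[.*\\]$", lines)]
  get_section <- function(nm) {
    i <- match(paste0("[", nm, "]"), names)
    if (is.na(i)) stop("profile file missing section [", nm, "]")
    body <- lines[sec == i]
    body[-1]
  }
  meta <- get_section("meta")
  name <- sub("^name=", "", grep("^name=", meta, value = TRUE)[1])
  if (is.na(name)) name <- "unnamed"
  ctx_lines <- get_section("contexts")
  parts <- strsplit(ctx_lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 8L)) {
    stop("malformed [contexts] line: ",
         ctx_lines[which(lengths(parts) != 8L)[1]])
  }
  ctx <- data.frame(
    kmer = vapply(parts, `[[`, character(1), 1),
    sub_rate = as.numeric(vapply(parts, `[[`, character(1), 2)),
    ins_rate = as.numeric(vapply(parts, `[[`, character(1), 3)),
    del_rate = as.numeric(vapply(parts, `[[`, character(1), 4)),
    sub_A = as.numeric(vapply(parts, `[[`, character(1), 5)),
    sub_C = as.numeric(vapply(parts, `[[`, character(1), 6)),
    sub_G = as.numeric(vapply(parts, `[[`, character(1), 7)),
    sub_T = as.numeric(vapply(parts, `[[`, character(1), 8)),
    stringsAsFactors = FALSE)
  miss <- setdiff(all_kmers3(), ctx$kmer)
  if (length(miss)) {
    stop("profile file missing context(s): ", paste(miss, collapse = ", "))
  }
  parse_dist <- function(nm) {
    rows <- strsplit(get_section(nm), "\t", fixed = TRUE)
    len <- as.integer(vapply(rows, `[[`, character(1), 1))
    p <- as.numeric(vapply(rows, `[[`, character(1), 2))
    d <- numeric(max(len))
    d[len] <- p
    d
  }
  error_profile(ctx, ins_len_dist = parse_dist("ins_lengths"),
                del_len_dist = parse_dist("del_lengths"), name = name)
}
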