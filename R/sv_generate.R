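#' Configuration for random SV generation
#'
#' @param counts_by_type named integer vector, e.g.
#'   `c(DEL = 100, INS = 100, DUP = 10)`
#' @param length_range named list of per-type `c(min, max)` length bounds in
#'   bp; lengths are drawn log-uniformly between the bounds. Types not listed
#'   fall back to the `default` entry.
#' @param telomere_window_bp size of the window at each chromosome end that
#'   counts as telomeric
#' @param telomere_weight relative per-position placement weight inside the
#'   telomere windows (1 = uniform; larger values concentrate SVs near the
#'   chromosome ends, mimicking the elevated SV density observed there)
#' @param het_fraction fraction of events simulated as heterozygous (split
#'   evenly between the two haplotypes); the rest are homozygous
#' @param seed integer seed; the whole placement is reproducible from it
#' @param max_rounds rejection-sampling rounds per type before giving up
#' @param toy relax the 50 bp minimum length
#' @return a list of class `sv_sim_config`
#' @export
sv_sim_config <- function(counts_by_type,
                          length_range = list(default = c(50, 10000)),
                          telomere_window_bp = 0L,
                          telomere_weight = 1,
                          het_fraction = 0.5,
                          seed = 1L,
                          max_rounds = 1000L,
                          toy = FALSE) {
  counts_by_type <- counts_by_type[counts_by_type > 0]
  stopifnot(all(names(counts_by_type) %in% SV_TYPES),
            telomere_weight >= 1, het_fraction >= 0, het_fraction <= 1)
  structure(list(counts_by_type = counts_by_type,
                 length_range = length_range,
                 telomere_window_bp = as.integer(telomere_window_bp),
                 telomere_weight = telomere_weight,
                 het_fraction = het_fraction,
                 seed = as.integer(seed),
                 max_rounds = as.integer(max_rounds),
                 toy = toy),
            class = "sv_sim_config")
}

## Log-uniform integer lengths in [lo, hi].
rloguniform <- function(n, lo, hi) {
  if (lo >= hi) return(rep(as.integer(lo), n))
  pmin(as.integer(round(exp(runif(n, log(lo), log(hi + 1))))), as.integer(hi))
}

#' Sample SV start positions with telomere bias
#'
#' Every position inside a telomere window (the first and last
#' `window` bp of each chromosome) carries `weight` times the placement
#' mass of a position outside, so the expected telomeric fraction is
#' `w*u / (1 + (w-1)*u)` where `u` is the uniform telomere mass
#' `sum(pmin(2*window, len)) / sum(len)`.
#'
#' @param n number of positions
#' @param chrom_lens named integer vector of chromosome lengths
#' @param window telomere window size in bp
#' @param weight telomeric per-position weight (>= 1)
#' @return data.frame with columns chrom, pos
#' @export
sample_sv_positions <- function(n, chrom_lens, window = 0L, weight = 1) {
  chrom <- character(n)
  pos <- integer(n)
  if (window > 0 && weight > 1) {
    telo_mass <- sum(pmin(2 * window, chrom_lens))
    u <- telo_mass / sum(chrom_lens)
    p_telo <- weight * u / (1 + (weight - 1) * u)
  } else {
    p_telo <- 0
  }
  in_telo <- runif(n) < p_telo
  k <- sum(in_telo)
  if (k > 0) {
    w <- pmin(2 * window, chrom_lens)
    ci <- sample.int(length(chrom_lens), k, replace = TRUE, prob = w)
    tl <- pmin(window, chrom_lens[ci])
    off <- as.integer(ceiling(runif(k) * tl))
    left <- runif(k) < 0.5
    pos[in_telo] <- ifelse(left, off, chrom_lens[ci] - off + 1L)
    chrom[in_telo] <- names(chrom_lens)[ci]
  }
  k <- sum(!in_telo)
  if (k > 0) {
    if (p_telo > 0) {
      ## complement of the telomere windows, so that telomeric and interior
      ## masses stay in the w*u : (1-u) proportion of the placement law
      interior <- pmax(chrom_lens - 2 * window, 0)
      if (all(interior == 0)) stop("telomere windows cover the whole genome")
      ci <- sample.int(length(chrom_lens), k, replace = TRUE, prob = interior)
      chrom[!in_telo] <- names(chrom_lens)[ci]
      pos[!in_telo] <- as.integer(window +
                                    ceiling(runif(k) * interior[ci]))
    } else {
      ci <- sample.int(length(chrom_lens), k, replace = TRUE,
                       prob = chrom_lens)
      chrom[!in_telo] <- names(chrom_lens)[ci]
      pos[!in_telo] <- as.integer(ceiling(runif(k) * chrom_lens[ci]))
    }
  }
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Generate random structural variants on a reference genome
#'
#' Events are placed with the configured telomere bias, with log-uniform
#' lengths per type, and rejection-sampled in vectorized rounds so that no
#' two events on the same haplotype overlap on the reference. CSUB
#' replacement sequence is copied from a randomly chosen distant locus of
#' the reference; INS sequence is random. TRA events exchange the tails of
#' two distinct chromosomes.
#'
#' @param config an [sv_sim_config()]
#' @param genome named character vector of chromosome sequences
#' @return validated SV event data.frame
#' @export
generate_random_svs <- function(config, genome) {
  genome <- as_seq_set(genome)
  chrom_lens <- nchar(genome)
  offsets <- setNames(cumsum(c(0, as.double(chrom_lens[-length(chrom_lens)] + 1))),
                      names(chrom_lens))
  with_seed(derive_seed(config$seed, "sv-placement"), {
    ## one global interval set: keeping haplotypes disjoint also on opposite
    ## haplotypes guarantees the merged all-SV sequence stays constructible
    acc <- IRanges::IRanges()
    rows <- list()
    counter <- 0L
    for (type in names(config$counts_by_type)) {
      n_want <- config$counts_by_type[[type]]
      if (type == "TRA" && n_want > length(genome) %/% 2L) {
        stop("each reciprocal translocation exchanges two chromosome ends; ",
             "at most floor(n_chroms/2) = ", length(genome) %/% 2L,
             " placeable")
      }
      lr <- config$length_range[[type]]
      if (is.null(lr)) lr <- config$length_range$default
      if (is.null(lr)) lr <- c(50, 10000)
      placed <- 0L
      round_i <- 0L
      while (placed < n_want) {
        round_i <- round_i + 1L
        if (round_i > config$max_rounds) {
          stop("could not place ", n_want, " ", type,
               " events without overlap; genome too small")
        }
        k <- n_want - placed
        len <- rloguniform(k, lr[1], lr[2])
        cand <- sample_sv_positions(k, chrom_lens,
                                    config$telomere_window_bp,
                                    config$telomere_weight)
        gt <- ifelse(runif(k) < config$het_fraction,
                     ifelse(runif(k) < 0.5, "HET_H1", "HET_H2"), "HOM")
        if (type == "TRA") {
          ## reciprocal end-segment exchange: the segment length follows the
          ## per-type length law, so the breakpoint is len-L+1 .. chrom end
          if (length(genome) < 2L) stop("TRA events need >= 2 chromosomes")
          cand$pos <- as.integer(chrom_lens[cand$chrom] - len + 1L)
        }
        span <- if (type == "INS") rep(0L, k) else len
        fits <- cand$pos >= 1L &
          cand$pos + pmax(span - 1L, 0L) <= chrom_lens[cand$chrom]
        if (!any(fits)) next
        len <- len[fits]; gt <- gt[fits]; span <- span[fits]
        cand <- cand[fits, , drop = FALSE]
        gstart <- offsets[cand$chrom] + cand$pos
        rng <- IRanges::IRanges(start = gstart,
                                width = pmax(span, 1L))
        drop <- IRanges::countOverlaps(rng, acc) > 0L
        ## self-overlaps within the round: keep the earlier candidate
        hits <- IRanges::findOverlaps(rng, rng)
        qh <- S4Vectors::queryHits(hits)
        sh <- S4Vectors::subjectHits(hits)
        sel <- which(qh < sh)
        for (j in sel[order(sh[sel])]) {
          if (!drop[qh[j]]) drop[sh[j]] <- TRUE
        }
        keep <- which(!drop)
        if (!length(keep)) next
        extra <- IRanges::IRanges()  # TRA partner tails reserved this round
        placed_idx <- integer(0)
        for (i in keep) {
          counter <- counter + 1L
          ev <- list(id = sprintf("rsv%05d", counter), chrom = cand$chrom[i],
                     start = cand$pos[i], ref_span = span[i],
                     length = len[i], sv_type = type, inserted_seq = "",
                     copies = 1L, genotype = gt[i],
                     chrom2 = NA_character_, pos2 = NA_integer_)
          if (type == "INS") {
            ev$inserted_seq <- int_to_dna(sample_bases_int(len[i]))
          } else if (type == "CSUB") {
            ins_len <- rloguniform(1L, lr[1], lr[2])
            seq <- random_distant_locus(genome, ev$chrom, ev$start, ins_len)
            if (is.null(seq)) { counter <- counter - 1L; next }
            ev$inserted_seq <- seq
            ev$length <- ins_len
          } else if (type == "TRA") {
            other <- sample(rep(setdiff(names(genome), ev$chrom), 2L), 1L)
            l2 <- rloguniform(1L, lr[1], min(lr[2], chrom_lens[[other]] - 1L))
            ev$chrom2 <- other
            ev$pos2 <- as.integer(chrom_lens[[other]] - l2 + 1L)
            partner <- IRanges::IRanges(start = offsets[other] + ev$pos2,
                                        width = l2)
            if (IRanges::countOverlaps(partner, acc) > 0L ||
                IRanges::countOverlaps(partner, rng[keep]) > 0L ||
                IRanges::countOverlaps(partner, extra) > 0L) {
              counter <- counter - 1L
              next
            }
            extra <- c(extra, partner)
          }
          rows[[length(rows) + 1L]] <- ev
          placed <- placed + 1L
          placed_idx <- c(placed_idx, i)
        }
        acc <- c(acc, rng[placed_idx], extra)
      }
    }
    df <- do.call(rbind, lapply(rows, as.data.frame,
                                stringsAsFactors = FALSE))
    sv_events(df, reference = genome, toy = config$toy)
  })
}

## Pick a random locus of the requested length at least 2x `len` away from
## the event being replaced; returns its sequence or NULL if none found.
random_distant_locus <- function(genome, avoid_chrom, avoid_pos, len) {
  lens <- nchar(genome)
  ok <- lens >= len + 1L
  if (!any(ok)) return(NULL)
  for (i in 1:50) {
    ch <- sample(rep(names(genome)[ok], 2L), 1L)
    st <- sample.int(lens[[ch]] - len + 1L, 1L)
    if (ch == avoid_chrom && abs(st - avoid_pos) < 2L * len) next
    return(substr(genome[[ch]], st, st + len - 1L))
  }
  NULL
}
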