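#' Alignment record for error-profile training
#'
#' A compact per-read summary of a pairwise alignment against the reference,
#' in reference orientation and 1-based reference coordinates: the aligned
#' interval, mismatch positions (with the read base observed there),
#' insertion points (the reference base 5' of the inserted run) and
#' deletion-run starts with their lengths.
#'
#' @param chrom reference sequence name
#' @param start,end first and last reference positions covered
#' @param sub_pos integer vector of mismatch positions
#' @param sub_alt character vector of read bases at `sub_pos` (may be empty)
#' @param ins_pos integer vector: reference base preceding each insertion
#' @param ins_len insertion lengths (bp)
#' @param del_pos integer vector: first deleted base of each deletion run
#' @param del_len deletion-run lengths (bp)
#' @return a list of class `aln_record`
#' @export
aln_record <- function(chrom, start, end, sub_pos = integer(0),
                       sub_alt = character(0), ins_pos = integer(0),
                       ins_len = integer(0), del_pos = integer(0),
                       del_len = integer(0)) {
  stopifnot(length(ins_pos) == length(ins_len),
            length(del_pos) == length(del_len))
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), sub_pos = as.integer(sub_pos),
                 sub_alt = as.character(sub_alt),
                 ins_pos = as.integer(ins_pos),
                 ins_len = as.integer(ins_len),
                 del_pos = as.integer(del_pos),
                 del_len = as.integer(del_len)),
            class = "aln_record")
}

#' Train a 3-mer error profile from alignments
#'
#' For every reference position with a full 3-mer context, the trainer
#' counts how often the position was reached by a read (matched, mismatched,
#' or the start of a deletion run; interior bases of a deletion run are not
#' independent observations and are excluded), how often it was substituted,
#' how often a deletion run started there, and how often an insertion
#' followed it. Rates are the per-context quotients; contexts never observed
#' receive the genome-wide mean rate. The first and last aligned column of
#' each read lack a symmetric context within the read and are skipped.
#' Insertion and deletion lengths are pooled into normalized length
#' distributions; runs longer than `l_max` are clipped with a warning (at
#' that size they are structural variants, not sequencing errors).
#'
#' @param alignments list of [aln_record()]s, or a SAM file path
#' @param reference named character vector of chromosome sequences
#' @param l_max longest indel carried by the length distributions
#' @param min_target_obs minimum per-context substitution count before the
#'   observed target-base distribution replaces the uniform default
#' @param name profile label
#' @return an [error_profile()]
#' @export
train_profile <- function(alignments, reference, l_max = 100L,
                          min_target_obs = 10L, name = "trained") {
  reference <- as_seq_set(reference)
  if (is.character(alignments) && length(alignments) == 1L) {
    alignments <- read_sam_records(alignments, reference)
  }
  stopifnot(length(alignments) > 0)
  chroms <- names(reference)
  ref_int <- lapply(reference, function(s) dna_to_int(s))
  kidx <- lapply(ref_int, kmer_index)

  reached_num <- setNames(lapply(chroms, function(ch) {
    numeric(nchar(reference[[ch]]) + 1L)
  }), chroms)
  delint_num <- reached_num
  sub_ct <- numeric(64)
  del_ct <- numeric(64)
  ins_ct <- numeric(64)
  tgt_ct <- matrix(0, 64, 4)
  ins_lens <- integer(0)
  del_lens <- integer(0)
  n_bases <- 0

  for (r in alignments) {
    if (!r$chrom %in% chroms) {
      stop("alignment references missing contig: ", r$chrom)
    }
    lo <- r$start + 1L
    hi <- r$end - 1L
    if (hi < lo) next
    n_bases <- n_bases + (hi - lo + 1L)
    reached_num[[r$chrom]][lo] <- reached_num[[r$chrom]][lo] + 1
    reached_num[[r$chrom]][hi + 1L] <- reached_num[[r$chrom]][hi + 1L] - 1
    ## deletion interiors were never reached independently
    if (length(r$del_pos)) {
      di_s <- pmax(r$del_pos + 1L, lo)
      di_e <- pmin(r$del_pos + r$del_len - 1L, hi)
      ok <- di_e >= di_s
      for (j in which(ok)) {
        delint_num[[r$chrom]][di_s[j]] <- delint_num[[r$chrom]][di_s[j]] + 1
        delint_num[[r$chrom]][di_e[j] + 1L] <-
          delint_num[[r$chrom]][di_e[j] + 1L] - 1
      }
    }
    interior <- function(p) p[p >= lo & p <= hi]
    k <- kidx[[r$chrom]]
    sp <- interior(r$sub_pos)
    if (length(sp)) {
      ki <- k[sp]
      sub_ct <- sub_ct + tabulate(ki, 64)
      if (length(r$sub_alt) == length(r$sub_pos)) {
        alt <- dna_to_int(paste(r$sub_alt, collapse = ""))
        keepi <- r$sub_pos >= lo & r$sub_pos <= hi
        ai <- alt[keepi] + 1L
        kk <- k[r$sub_pos[keepi]]
        for (j in seq_along(ai)) {
          if (!is.na(kk[j]) && !is.na(ai[j])) {
            tgt_ct[kk[j], ai[j]] <- tgt_ct[kk[j], ai[j]] + 1
          }
        }
      }
    }
    ## runs ending at the last aligned column may have been clipped by the
    ## read end; excluding them removes exactly one start position per run
    ## length, so the length distribution stays unbiased
    dkeep <- r$del_pos >= lo & r$del_pos <= hi &
      r$del_pos + r$del_len - 1L < r$end
    if (any(dkeep)) {
      del_ct <- del_ct + tabulate(k[r$del_pos[dkeep]], 64)
      del_lens <- c(del_lens, r$del_len[dkeep])
    }
    ikeep <- r$ins_pos >= lo & r$ins_pos <= hi &
      !(r$ins_pos %in% c(r$del_pos, unlist(lapply(seq_along(r$del_pos),
        function(j) seq(r$del_pos[j], length.out = r$del_len[j])))))
    if (any(ikeep)) {
      ins_ct <- ins_ct + tabulate(k[r$ins_pos[ikeep]], 64)
      ins_lens <- c(ins_lens, r$ins_len[ikeep])
    }
  }
  if (n_bases == 0) stop("no aligned bases to train from")

  denom <- numeric(64)
  for (ch in chroms) {
    reach <- cumsum(reached_num[[ch]]) - cumsum(delint_num[[ch]])
    reach <- reach[seq_len(nchar(reference[[ch]]))]
    k <- kidx[[ch]]
    ok <- !is.na(k) & reach > 0
    if (any(ok)) {
      agg <- vapply(split(reach[ok], k[ok]), sum, numeric(1))
      at <- as.integer(names(agg))
      denom[at] <- denom[at] + agg
    }
  }
  emit_denom <- pmax(denom - del_ct, 0)

  seen <- denom > 0
  sub_rate <- ifelse(seen, sub_ct / pmax(denom, 1), NA)
  del_rate <- ifelse(seen, del_ct / pmax(denom, 1), NA)
  ins_rate <- ifelse(emit_denom > 0, ins_ct / pmax(emit_denom, 1), NA)
  fill_mean <- function(r) {
    m <- if (all(is.na(r))) 0 else mean(r, na.rm = TRUE)
    ifelse(is.na(r), m, r)
  }
  sub_rate <- fill_mean(sub_rate)
  del_rate <- fill_mean(del_rate)
  ins_rate <- fill_mean(ins_rate)

  kmers <- all_kmers3()
  mid_i <- match(substr(kmers, 2, 2), BASES)
  tgt <- matrix(1 / 3, 64, 4)
  tgt[cbind(1:64, mid_i)] <- 0
  rs <- rowSums(tgt_ct)
  for (i in which(rs >= min_target_obs)) {
    tgt[i, ] <- tgt_ct[i, ] / rs[i]
  }
  colnames(tgt) <- paste0("sub_", BASES)

  clip_lens <- function(lens, what) {
    if (any(lens > l_max)) {
      warning(sum(lens > l_max), " ", what, " run(s) longer than l_max = ",
              l_max, " clipped (SV-scale, not sequencing error)")
      lens <- pmin(lens, l_max)
    }
    lens
  }
  make_dist <- function(lens, what) {
    if (!length(lens)) return(1)
    lens <- clip_lens(lens, what)
    tabulate(lens, max(lens)) / length(lens)
  }
  ctx <- data.frame(kmer = kmers, sub_rate = sub_rate, ins_rate = ins_rate,
                    del_rate = del_rate, stringsAsFactors = FALSE)
  ctx <- cbind(ctx, as.data.frame(tgt))
  out <- error_profile(ctx, ins_len_dist = make_dist(ins_lens, "insertion"),
                       del_len_dist = make_dist(del_lens, "deletion"),
                       name = name)
  ## raw tabulation, for standard errors and goodness-of-fit downstream
  attr(out, "training") <- list(
    denom = denom, emit_denom = emit_denom,
    sub_ct = sub_ct, ins_ct = ins_ct, del_ct = del_ct,
    ins_len_counts = tabulate(pmin(ins_lens, l_max),
                              max(c(ins_lens, 1L))),
    del_len_counts = tabulate(pmin(del_lens, l_max),
                              max(c(del_lens, 1L))))
  out
}

#' Read a SAM file into alignment records
#'
#' Text SAM only (convert BAM with `samtools view` if needed). Handles CIGAR
#' operations M/=/X/I/D and skips S/H-clipped bases; mismatches inside M
#' runs are recovered by comparison against the reference. Reverse-strand
#' alignments need no special handling because SAM stores SEQ already in
#' reference orientation.
#'
#' @param path SAM file
#' @param reference named character vector of chromosome sequences
#' @return list of [aln_record()]s
#' @export
read_sam_records <- function(path, reference) {
  reference <- as_seq_set(reference)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L) stop("malformed SAM record")
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) next  # unmapped
    chrom <- f[3]
    if (!chrom %in% names(reference)) {
      stop("SAM record references missing contig: ", chrom)
    }
    pos <- as.integer(f[4])
    cigar <- f[6]
    seq <- toupper(f[10])
    ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    kind <- sub("^\\d+", "", ops)
    rp <- pos          # reference pointer
    qp <- 1L           # read pointer
    sub_pos <- integer(0); sub_alt <- character(0)
    ins_pos <- integer(0); ins_len <- integer(0)
    del_pos <- integer(0); del_len <- integer(0)
    for (j in seq_along(kind)) {
      L <- lens[j]
      op <- kind[j]
      if (op %in% c("M", "=", "X")) {
        refseg <- substr(reference[[chrom]], rp, rp + L - 1L)
        readseg <- substr(seq, qp, qp + L - 1L)
        if (op == "X" || (op == "M" && refseg != readseg)) {
          rb <- strsplit(refseg, "")[[1]]
          qb <- strsplit(readseg, "")[[1]]
          mm <- which(rb != qb)
          sub_pos <- c(sub_pos, rp + mm - 1L)
          sub_alt <- c(sub_alt, qb[mm])
        }
        rp <- rp + L; qp <- qp + L
      } else if (op == "I") {
        ins_pos <- c(ins_pos, rp - 1L)
        ins_len <- c(ins_len, L)
        qp <- qp + L
      } else if (op %in% c("D", "N")) {
        del_pos <- c(del_pos, rp)
        del_len <- c(del_len, L)
        rp <- rp + L
      } else if (op == "S") {
        qp <- qp + L
      }  # H/P consume nothing here
    }
    out[[length(out) + 1L]] <- aln_record(chrom, pos, rp - 1L, sub_pos,
                                          sub_alt, ins_pos, ins_len,
                                          del_pos, del_len)
  }
  out
}

#' Align reads to a reference and produce alignment records
#'
#' Toy-scale helper so profile training does not require an external
#' aligner: each read is aligned locally against its chromosome with
#' [Biostrings::pairwiseAlignment()] and converted to an [aln_record()].
#' Intended for small genomes and read sets only.
#'
#' @param reads named character vector of read sequences
#' @param reference named character vector; single chromosome required per
#'   call unless `chrom` is given per read
#' @param chrom chromosome to align against (default: first)
#' @return list of [aln_record()]s
#' @export
align_reads_to_reference <- function(reads, reference,
                                     chrom = names(as_seq_set(reference))[1]) {
  reference <- as_seq_set(reference)
  subject <- Biostrings::DNAString(reference[[chrom]])
  lapply(seq_along(reads), function(i) {
    fwd <- Biostrings::pairwiseAlignment(reads[[i]], subject,
                                         type = "local")
    rev <- Biostrings::pairwiseAlignment(revcomp_chr(reads[[i]]), subject,
                                         type = "local")
    aln <- if (Biostrings::score(fwd) >= Biostrings::score(rev)) fwd else rev
    pattern_chars <- strsplit(as.character(Biostrings::alignedPattern(aln)),
                              "")[[1]]
    subject_chars <- strsplit(as.character(Biostrings::alignedSubject(aln)),
                              "")[[1]]
    start <- Biostrings::start(Biostrings::subject(aln))
    rp <- start - 1L
    sub_pos <- integer(0); sub_alt <- character(0)
    ins_pos <- integer(0); ins_len <- integer(0)
    del_pos <- integer(0); del_len <- integer(0)
    j <- 1L
    n <- length(pattern_chars)
    while (j <= n) {
      pc <- pattern_chars[j]; sc <- subject_chars[j]
      if (sc == "-") {          # insertion relative to the reference
        L <- 0L
        while (j <= n && subject_chars[j] == "-") { L <- L + 1L; j <- j + 1L }
        ins_pos <- c(ins_pos, rp); ins_len <- c(ins_len, L)
      } else if (pc == "-") {   # deletion
        L <- 0L
        st <- rp + 1L
        while (j <= n && pattern_chars[j] == "-") {
          L <- L + 1L; rp <- rp + 1L; j <- j + 1L
        }
        del_pos <- c(del_pos, st); del_len <- c(del_len, L)
      } else {
        rp <- rp + 1L
        if (pc != sc) { sub_pos <- c(sub_pos, rp); sub_alt <- c(sub_alt, pc) }
        j <- j + 1L
      }
    }
    aln_record(chrom, start, rp, sub_pos, sub_alt, ins_pos, ins_len,
               del_pos, del_len)
  })
}
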