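#' Apply structural variants to a reference genome
#'
#' Produces the two haplotype sequence sets of a diploid sample plus a
#' merged set in which every event is applied homozygously. Events tagged
#' HOM appear on both haplotypes, HET_H1/HET_H2 on exactly one. All event
#' coordinates refer to the reference, and events on the same haplotype must
#' not overlap, so each chromosome can be rebuilt in a single left-to-right
#' pass (equivalent to editing right-to-left with stored coordinates).
#'
#' Event semantics: DEL removes `ref_span` bp starting at `start`; INS
#' inserts `inserted_seq` after position `start`; DUP appends `copies` extra
#' tandem copies after the duplicated unit; INVDUP appends `copies`
#' reverse-complemented copies; INV reverse-complements the region in place;
#' CSUB replaces the `ref_span` bp region with `inserted_seq`; TRA
#' reciprocally exchanges the chromosome tails starting at `start` (on
#' `chrom`) and `pos2` (on `chrom2`).
#'
#' @param reference named character vector (or DNAStringSet) of chromosomes
#' @param events validated SV event data.frame ([sv_events()])
#' @param toy relax the 50 bp minimum during validation
#' @return list with elements `hap1`, `hap2`, `merged` (named character
#'   vectors) and `applied` (the events with per-haplotype coordinates
#'   `pos_h1`, `pos_h2`, `pos_merged` in the derived sequences)
#' @export
apply_svs <- function(reference, events, toy = FALSE) {
  reference <- as_seq_set(reference)
  events <- sv_events(events, reference = reference, toy = toy)
  hap1 <- apply_to_haplotype(reference, events[events$genotype != "HET_H2", ])
  hap2 <- apply_to_haplotype(reference, events[events$genotype != "HET_H1", ])
  merged <- apply_to_haplotype(reference, events)
  applied <- events
  applied$pos_h1 <- hap_coordinates(reference, events, events$genotype != "HET_H2")
  applied$pos_h2 <- hap_coordinates(reference, events, events$genotype != "HET_H1")
  applied$pos_merged <- hap_coordinates(reference, events,
                                        rep(TRUE, nrow(events)))
  list(hap1 = hap1, hap2 = hap2, merged = merged, applied = applied)
}

## Cut intervals and replacement sequences of one event on one chromosome.
## A pure insertion is a zero-width cut: cut_end == cut_start - 1.
event_edits <- function(ev, reference) {
  seq_of <- function(ch, s, e) substr(reference[[ch]], s, e)
  s <- ev$start
  switch(ev$sv_type,
    DEL = list(list(chrom = ev$chrom, s = s, e = s + ev$ref_span - 1L,
                    repl = "")),
    INS = list(list(chrom = ev$chrom, s = s + 1L, e = s,
                    repl = ev$inserted_seq)),
    CSUB = list(list(chrom = ev$chrom, s = s, e = s + ev$ref_span - 1L,
                     repl = ev$inserted_seq)),
    INV = {
      unit <- seq_of(ev$chrom, s, s + ev$length - 1L)
      list(list(chrom = ev$chrom, s = s, e = s + ev$length - 1L,
                repl = revcomp_chr(unit)))
    },
    DUP = {
      unit <- seq_of(ev$chrom, s, s + ev$length - 1L)
      list(list(chrom = ev$chrom, s = s, e = s + ev$length - 1L,
                repl = paste(rep(unit, 1L + ev$copies), collapse = "")))
    },
    INVDUP = {
      unit <- seq_of(ev$chrom, s, s + ev$length - 1L)
      list(list(chrom = ev$chrom, s = s, e = s + ev$length - 1L,
                repl = paste0(unit, paste(rep(revcomp_chr(unit), ev$copies),
                                          collapse = ""))))
    },
    TRA = {
      l1 <- nchar(reference[[ev$chrom]])
      l2 <- nchar(reference[[ev$chrom2]])
      list(list(chrom = ev$chrom, s = s, e = l1,
                repl = seq_of(ev$chrom2, ev$pos2, l2)),
           list(chrom = ev$chrom2, s = ev$pos2, e = l2,
                repl = seq_of(ev$chrom, s, l1)))
    },
    stop("unhandled sv_type: ", ev$sv_type)
  )
}

## Rebuild every chromosome with the given events applied.
apply_to_haplotype <- function(reference, events) {
  edits <- list()
  for (i in seq_len(nrow(events))) {
    edits <- c(edits, event_edits(events[i, ], reference))
  }
  out <- reference
  for (ch in names(reference)) {
    ed <- Filter(function(e) e$chrom == ch, edits)
    if (!length(ed)) next
    ord <- order(vapply(ed, `[[`, numeric(1), "s"))
    ed <- ed[ord]
    starts <- vapply(ed, `[[`, numeric(1), "s")
    ends <- vapply(ed, `[[`, numeric(1), "e")
    if (any(starts[-1] <= cummax(ends + 1)[-length(ed)] - 1)) {
      stop("overlapping events on chromosome ", ch)
    }
    pieces <- character(2L * length(ed) + 1L)
    prev_end <- 0L
    for (j in seq_along(ed)) {
      pieces[2L * j - 1L] <- substr(reference[[ch]], prev_end + 1L,
                                    starts[j] - 1L)
      pieces[2L * j] <- ed[[j]]$repl
      prev_end <- ends[j]
    }
    pieces[2L * length(ed) + 1L] <- substr(reference[[ch]], prev_end + 1L,
                                           nchar(reference[[ch]]))
    out[[ch]] <- paste(pieces, collapse = "")
  }
  out
}

## Position of each event in the derived haplotype sequence (NA when the
## event is absent from that haplotype): reference start shifted by the
## length deltas of all preceding events on the same chromosome.
hap_coordinates <- function(reference, events, present) {
  pos <- rep(NA_integer_, nrow(events))
  deltas <- sv_length_delta(events)
  for (ch in unique(events$chrom)) {
    idx <- which(present & events$chrom == ch)
    if (!length(idx)) next
    idx <- idx[order(events$start[idx])]
    shift <- cumsum(c(0L, deltas[idx]))[seq_along(idx)]
    pos[idx] <- events$start[idx] + shift
  }
  pos
}
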