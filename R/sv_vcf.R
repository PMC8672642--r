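#' Write a truth set of structural variants as VCF 4.2
#'
#' DEL, INS and CSUB are written sequence-resolved with the usual anchor-base
#' convention (POS is the base before the event; events starting at position
#' 1 are right-anchored instead). DUP, INVDUP and INV use symbolic ALT
#' alleles with SVLEN/END INFO keys, and each TRA is emitted as a pair of
#' BND records linked by MATEID/EVENT. Genotypes are written phased
#' (`1|0` = haplotype 1, `0|1` = haplotype 2, `1/1` = homozygous) so that
#' the file round-trips through [parse_sv_list()].
#'
#' @param events validated SV event data.frame
#' @param reference named character vector of chromosome sequences
#' @param path output path
#' @return the path, invisibly
#' @export
write_truth_vcf <- function(events, reference, path) {
  reference <- as_seq_set(reference)
  events <- sv_events(events, reference = reference, toy = TRUE)
  extra <- c(
    '##INFO=<ID=REFSPAN,Number=1,Type=Integer,Description="Reference bp replaced by a CSUB">',
    '##INFO=<ID=COPIES,Number=1,Type=Integer,Description="Extra tandem copies">',
    '##INFO=<ID=CHR2,Number=1,Type=String,Description="Partner chromosome of a TRA">',
    '##INFO=<ID=END2,Number=1,Type=Integer,Description="Partner breakpoint of a TRA">',
    '##INFO=<ID=EVENT,Number=1,Type=String,Description="Event id grouping BND mates">',
    '##INFO=<ID=MATEID,Number=1,Type=String,Description="Mate breakend id">',
    '##ALT=<ID=DUP,Description="Tandem duplication">',
    '##ALT=<ID=INVDUP,Description="Inverted tandem duplication">',
    '##ALT=<ID=INV,Description="Inversion">')
  rows <- lapply(seq_len(nrow(events)), function(i) {
    truth_vcf_row(events[i, ], reference)
  })
  rec <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(rec)) {
    rec <- data.frame(chrom = character(0), pos = integer(0),
                      id = character(0), ref = character(0),
                      alt = character(0), qual = character(0),
                      filter = character(0), info = character(0),
                      format = character(0), sample = character(0))
  }
  write_vcf_lines(vcf_header(reference, extra, sample = "SIM"), rec, path)
}

gt_string <- function(genotype) {
  switch(genotype, HOM = "1/1", HET_H1 = "1|0", HET_H2 = "0|1")
}

gt_to_genotype <- function(gt) {
  gt <- sub(":.*$", "", gt)
  switch(gt,
         "1/1" = , "1|1" = "HOM",
         "1|0" = , "1/0" = , "0/1" = "HET_H1",
         "0|1" = "HET_H2",
         stop("cannot interpret GT: ", gt))
}

## One (or, for TRA, two) VCF body rows for a single event.
truth_vcf_row <- function(ev, reference) {
  base_at <- function(ch, p) substr(reference[[ch]], p, p)
  region <- function(ch, s, e) substr(reference[[ch]], s, e)
  gt <- gt_string(ev$genotype)
  row <- function(chrom, pos, id, ref, alt, info) {
    data.frame(chrom = chrom, pos = as.integer(pos), id = id, ref = ref,
               alt = alt, qual = ".", filter = "PASS", info = info,
               format = "GT", sample = gt, stringsAsFactors = FALSE)
  }
  s <- ev$start
  if (ev$sv_type == "DEL") {
    e <- s + ev$ref_span - 1L
    if (s > 1L) {
      anc <- base_at(ev$chrom, s - 1L)
      return(row(ev$chrom, s - 1L, ev$id, paste0(anc, region(ev$chrom, s, e)),
                 anc, sprintf("SVTYPE=DEL;SVLEN=%d;END=%d", -ev$length, e)))
    }
    anc <- base_at(ev$chrom, e + 1L)
    return(row(ev$chrom, 1L, ev$id, paste0(region(ev$chrom, s, e), anc), anc,
               sprintf("SVTYPE=DEL;SVLEN=%d;END=%d", -ev$length, e)))
  }
  if (ev$sv_type == "INS") {
    anc <- base_at(ev$chrom, s)
    return(row(ev$chrom, s, ev$id, anc, paste0(anc, ev$inserted_seq),
               sprintf("SVTYPE=INS;SVLEN=%d;END=%d", ev$length, s)))
  }
  if (ev$sv_type == "CSUB") {
    e <- s + ev$ref_span - 1L
    if (s > 1L) {
      anc <- base_at(ev$chrom, s - 1L)
      return(row(ev$chrom, s - 1L, ev$id, paste0(anc, region(ev$chrom, s, e)),
                 paste0(anc, ev$inserted_seq),
                 sprintf("SVTYPE=CSUB;SVLEN=%d;END=%d;REFSPAN=%d",
                         ev$length, e, ev$ref_span)))
    }
    anc <- base_at(ev$chrom, e + 1L)
    return(row(ev$chrom, 1L, ev$id, paste0(region(ev$chrom, s, e), anc),
               paste0(ev$inserted_seq, anc),
               sprintf("SVTYPE=CSUB;SVLEN=%d;END=%d;REFSPAN=%d",
                       ev$length, e, ev$ref_span)))
  }
  if (ev$sv_type %in% c("DUP", "INVDUP", "INV")) {
    e <- s + ev$length - 1L
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", ev$sv_type, ev$length, e)
    if (ev$sv_type %in% c("DUP", "INVDUP")) {
      info <- paste0(info, ";COPIES=", ev$copies)
    }
    return(row(ev$chrom, s, ev$id, base_at(ev$chrom, s),
               paste0("<", ev$sv_type, ">"), info))
  }
  if (ev$sv_type == "TRA") {
    p1 <- max(s - 1L, 1L)
    p2 <- max(ev$pos2 - 1L, 1L)
    b1 <- base_at(ev$chrom, p1)
    b2 <- base_at(ev$chrom2, p2)
    id1 <- paste0(ev$id, "_1")
    id2 <- paste0(ev$id, "_2")
    info1 <- sprintf(
      "SVTYPE=BND;EVENT=%s;MATEID=%s;CHR2=%s;END2=%d;SVLEN=%d",
      ev$id, id2, ev$chrom2, ev$pos2, ev$length)
    info2 <- sprintf("SVTYPE=BND;EVENT=%s;MATEID=%s;CHR2=%s;END2=%d",
                     ev$id, id1, ev$chrom, s)
    return(rbind(
      row(ev$chrom, p1, id1, b1,
          sprintf("%s[%s:%d[", b1, ev$chrom2, ev$pos2), info1),
      row(ev$chrom2, p2, id2, b2,
          sprintf("%s[%s:%d[", b2, ev$chrom, s), info2)))
  }
  stop("unhandled sv_type: ", ev$sv_type)
}

## Reconstruct SV events from a truth VCF written by write_truth_vcf().
parse_truth_vcf <- function(path, reference = NULL, toy = FALSE) {
  v <- read_vcf_records(path)
  rec <- v$records
  if (!nrow(rec)) {
    return(sv_events(data.frame(chrom = character(0), start = integer(0),
                                sv_type = character(0), length = integer(0)),
                     toy = toy))
  }
  svtype <- info_field(rec$info, "SVTYPE")
  svlen <- as.integer(info_field(rec$info, "SVLEN"))
  end <- as.integer(info_field(rec$info, "END"))
  rows <- list()
  bnd <- which(svtype == "BND")
  for (i in setdiff(seq_len(nrow(rec)), bnd)) {
    ty <- svtype[i]
    gt <- gt_to_genotype(rec$sample[i])
    if (ty == "DEL") {
      len <- abs(svlen[i])
      rows[[length(rows) + 1L]] <- data.frame(
        id = rec$id[i], chrom = rec$chrom[i], start = end[i] - len + 1L,
        ref_span = len, length = len, sv_type = "DEL", inserted_seq = "",
        copies = 1L, genotype = gt, chrom2 = NA_character_,
        pos2 = NA_integer_, stringsAsFactors = FALSE)
    } else if (ty == "INS") {
      seq <- substr(rec$alt[i], 2L, nchar(rec$alt[i]))
      rows[[length(rows) + 1L]] <- data.frame(
        id = rec$id[i], chrom = rec$chrom[i], start = rec$pos[i],
        ref_span = 0L, length = nchar(seq), sv_type = "INS",
        inserted_seq = seq, copies = 1L, genotype = gt,
        chrom2 = NA_character_, pos2 = NA_integer_, stringsAsFactors = FALSE)
    } else if (ty == "CSUB") {
      span <- as.integer(info_field(rec$info[i], "REFSPAN"))
      start <- end[i] - span + 1L
      seq <- if (rec$pos[i] == start - 1L) {
        substr(rec$alt[i], 2L, nchar(rec$alt[i]))
      } else {
        substr(rec$alt[i], 1L, nchar(rec$alt[i]) - 1L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = rec$id[i], chrom = rec$chrom[i], start = start,
        ref_span = span, length = nchar(seq), sv_type = "CSUB",
        inserted_seq = seq, copies = 1L, genotype = gt,
        chrom2 = NA_character_, pos2 = NA_integer_, stringsAsFactors = FALSE)
    } else if (ty %in% c("DUP", "INVDUP", "INV")) {
      cp <- as.integer(info_field(rec$info[i], "COPIES"))
      rows[[length(rows) + 1L]] <- data.frame(
        id = rec$id[i], chrom = rec$chrom[i], start = rec$pos[i],
        ref_span = svlen[i], length = svlen[i], sv_type = ty,
        inserted_seq = "", copies = ifelse(is.na(cp), 1L, cp),
        genotype = gt, chrom2 = NA_character_, pos2 = NA_integer_,
        stringsAsFactors = FALSE)
    } else {
      stop("unknown SVTYPE in truth VCF: ", ty)
    }
  }
  if (length(bnd)) {
    ev_id <- info_field(rec$info[bnd], "EVENT")
    for (eid in unique(ev_id)) {
      grp <- bnd[ev_id == eid]
      first <- grp[endsWith(rec$id[grp], "_1")][1]
      if (is.na(first)) stop("BND group without a primary mate: ", eid)
      i <- first
      start <- as.integer(info_field(rec$info[setdiff(grp, i)[1]], "END2"))
      len <- svlen[i]
      rows[[length(rows) + 1L]] <- data.frame(
        id = eid, chrom = rec$chrom[i], start = start,
        ref_span = len, length = len, sv_type = "TRA", inserted_seq = "",
        copies = 1L, genotype = gt_to_genotype(rec$sample[i]),
        chrom2 = info_field(rec$info[i], "CHR2"),
        pos2 = as.integer(info_field(rec$info[i], "END2")),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(match(df$id, rec$id)), ]
  sv_events(df, reference = reference, toy = toy)
}
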