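#' Construct and validate a set of structural-variant events
#'
#' An SV event set is a data.frame with one row per event and the columns
#' `id`, `chrom`, `start` (1-based, inclusive, on the reference), `ref_span`
#' (reference bp consumed; 0 for pure insertions), `length` (size of the
#' variant in bp), `sv_type` (one of DEL, INS, DUP, INVDUP, INV, TRA, CSUB),
#' `inserted_seq` (INS/CSUB only, otherwise ""), `copies` (extra tandem
#' copies for DUP/INVDUP, otherwise 1), `genotype` (HET_H1, HET_H2 or HOM),
#' and, for TRA only, `chrom2`/`pos2` naming the reciprocal partner
#' breakpoint (NA otherwise).
#'
#' Structural variants are defined as events of at least 50 bp; `toy = TRUE`
#' relaxes that floor so that worked examples can stay small.
#'
#' @param df data.frame carrying at least chrom, start, sv_type and length
#' @param reference optional named character vector of chromosome sequences;
#'   when supplied, coordinates are checked against chromosome bounds
#' @param toy logical; relax the 50 bp minimum length
#' @return the validated event data.frame, with defaults filled in
#' @export
sv_events <- function(df, reference = NULL, toy = FALSE) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "sv_type", "length")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing SV columns: ", paste(miss, collapse = ", "))
  n <- nrow(df)
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$sv_type <- toupper(as.character(df$sv_type))
  df$length <- as.integer(df$length)
  if (is.null(df$id)) df$id <- sprintf("sv%05d", seq_len(n))
  if (is.null(df$inserted_seq)) df$inserted_seq <- ""
  df$inserted_seq <- toupper(ifelse(is.na(df$inserted_seq), "",
                                    as.character(df$inserted_seq)))
  if (is.null(df$copies)) df$copies <- 1L
  df$copies[is.na(df$copies)] <- 1L
  df$copies <- as.integer(df$copies)
  if (is.null(df$genotype)) df$genotype <- "HOM"
  df$genotype <- toupper(as.character(df$genotype))
  if (is.null(df$ref_span)) {
    df$ref_span <- ifelse(df$sv_type == "INS", 0L, df$length)
  }
  df$ref_span <- as.integer(df$ref_span)
  if (is.null(df$chrom2)) df$chrom2 <- NA_character_
  if (is.null(df$pos2)) df$pos2 <- NA_integer_
  df$pos2 <- as.integer(df$pos2)

  bad_type <- !df$sv_type %in% SV_TYPES
  if (any(bad_type)) {
    stop("unknown sv_type: ", paste(unique(df$sv_type[bad_type]), collapse = ", "))
  }
  bad_gt <- !df$genotype %in% GENOTYPES
  if (any(bad_gt)) {
    stop("unknown genotype: ", paste(unique(df$genotype[bad_gt]), collapse = ", "))
  }
  min_len <- if (toy) 1L else 50L
  if (any(df$length < min_len)) {
    stop("SV length below the ", min_len, " bp minimum (SVs are >= 50 bp; ",
         "use toy = TRUE for small worked examples)")
  }
  if (any(df$start < 1L)) stop("start positions must be >= 1")
  if (any(df$copies < 1L)) stop("copies must be >= 1")

  ins <- df$sv_type == "INS"
  if (any(ins & nchar(df$inserted_seq) == 0L)) {
    stop("INS events require inserted_seq")
  }
  if (any(ins & df$ref_span != 0L)) stop("INS events must have ref_span 0")
  if (any(ins & nchar(df$inserted_seq) != df$length)) {
    stop("INS length must equal nchar(inserted_seq)")
  }
  csub <- df$sv_type == "CSUB"
  if (any(csub & nchar(df$inserted_seq) != df$length)) {
    stop("CSUB length must equal nchar(inserted_seq)")
  }
  if (any(csub & df$ref_span < min_len)) {
    stop("CSUB ref_span below the ", min_len, " bp minimum")
  }
  fixed <- df$sv_type %in% c("DEL", "INV", "DUP", "INVDUP")
  if (any(fixed & df$ref_span != df$length)) {
    stop("DEL/INV/DUP/INVDUP events must have ref_span == length")
  }
  tra <- df$sv_type == "TRA"
  if (any(tra & (is.na(df$chrom2) | is.na(df$pos2)))) {
    stop("TRA events require chrom2 and pos2")
  }

  if (!is.null(reference)) {
    ref <- as_seq_set(reference)
    bad_chr <- !df$chrom %in% names(ref)
    if (any(bad_chr)) {
      stop("chromosome not in reference: ",
           paste(unique(df$chrom[bad_chr]), collapse = ", "))
    }
    ends <- df$start + pmax(df$ref_span - 1L, 0L)
    too_far <- ends > nchar(ref)[match(df$chrom, names(ref))]
    if (any(too_far)) {
      stop("event extends past chromosome end: ",
           paste(df$id[too_far], collapse = ", "))
    }
  }

  cols <- c("id", "chrom", "start", "ref_span", "length", "sv_type",
            "inserted_seq", "copies", "genotype", "chrom2", "pos2")
  rownames(df) <- NULL
  df[, cols]
}

#' Signed per-event change in haplotype length
#'
#' Insertions add `length` bp, deletions remove `ref_span` bp, tandem and
#' inverted duplications add `length * copies` bp, complex substitutions add
#' `length - ref_span` bp, and inversions and reciprocal translocations leave
#' the total haplotype length unchanged.
#'
#' @param events validated SV event data.frame
#' @return integer vector of per-event length deltas (bp)
#' @export
sv_length_delta <- function(events) {
  delta <- integer(nrow(events))
  t <- events$sv_type
  delta[t == "INS"] <- events$length[t == "INS"]
  delta[t == "DEL"] <- -events$ref_span[t == "DEL"]
  dup <- t %in% c("DUP", "INVDUP")
  delta[dup] <- events$length[dup] * events$copies[dup]
  delta[t == "CSUB"] <- events$length[t == "CSUB"] - events$ref_span[t == "CSUB"]
  delta
}

#' Read a truth list of structural variants
#'
#' Accepts either a tab-separated truth list with columns
#' `chrom, pos, type, length[, seq][, genotype][, copies]` (header required)
#' or a VCF produced by [write_truth_vcf()]. Invalid records raise an error
#' rather than being skipped.
#'
#' @param path file path
#' @param reference optional named character vector for coordinate checks
#' @param toy relax the 50 bp minimum (worked examples)
#' @return validated SV event data.frame (see [sv_events()])
#' @export
parse_sv_list <- function(path, reference = NULL, toy = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF") || grepl("\\.vcf$", path)) {
    return(parse_truth_vcf(path, reference = reference, toy = toy))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  names(tab) <- tolower(names(tab))
  ren <- c(pos = "start", type = "sv_type", seq = "inserted_seq")
  for (i in seq_along(ren)) {
    if (names(ren)[i] %in% names(tab)) {
      names(tab)[names(tab) == names(ren)[i]] <- ren[[i]]
    }
  }
  sv_events(tab, reference = reference, toy = toy)
}

#' Write a truth list TSV
#'
#' @param events validated SV event data.frame
#' @param path output path
#' @return the path, invisibly
#' @export
write_sv_list <- function(events, path) {
  out <- data.frame(chrom = events$chrom, pos = events$start,
                    type = events$sv_type, length = events$length,
                    seq = events$inserted_seq, genotype = events$genotype,
                    copies = events$copies, ref_span = events$ref_span,
                    chrom2 = events$chrom2, pos2 = events$pos2,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
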