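## Minimal line-oriented VCF reading/writing shared by the truth-set,
## benchmark and combiner modules. SV caller VCFs in the wild are frequently
## not schema-clean (symbolic ALTs, INFO keys missing from the header,
## caller-specific support fields in INFO or FORMAT), so records are parsed
## tolerantly into a plain data.frame and INFO/FORMAT fields are extracted
## by key on demand.

read_vcf_records <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "##")]
  col_line <- lines[startsWith(lines, "#CHROM")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) {
    return(list(header = hdr,
                records = data.frame(chrom = character(0), pos = integer(0),
                                     id = character(0), ref = character(0),
                                     alt = character(0), qual = character(0),
                                     filter = character(0), info = character(0),
                                     format = character(0), sample = character(0),
                                     stringsAsFactors = FALSE)))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 8L)) stop("malformed VCF record (fewer than 8 columns)")
  grab <- function(i) vapply(parts, function(p) {
    if (length(p) >= i) p[[i]] else ""
  }, character(1))
  rec <- data.frame(chrom = grab(1), pos = as.integer(grab(2)), id = grab(3),
                    ref = grab(4), alt = grab(5), qual = grab(6),
                    filter = grab(7), info = grab(8), format = grab(9),
                    sample = grab(10), stringsAsFactors = FALSE)
  list(header = hdr, records = rec)
}

## Value of `key` in an INFO string vector; NA when absent. Flag keys
## (present without "=") return "TRUE".
info_field <- function(info, key) {
  out <- rep(NA_character_, length(info))
  pat <- paste0("(^|;)", key, "=([^;]*)")
  hit <- regexpr(pat, info)
  has <- hit > 0
  out[has] <- sub(paste0(".*(^|;)", key, "=([^;]*).*"), "\\2", info[has])
  flag <- !has & grepl(paste0("(^|;)", key, "(;|$)"), info)
  out[flag] <- "TRUE"
  out
}

## Value of `key` in FORMAT/sample column pairs; NA when absent.
format_field <- function(format, sample, key) {
  mapply(function(f, s) {
    if (is.na(f) || !nzchar(f)) return(NA_character_)
    keys <- strsplit(f, ":", fixed = TRUE)[[1]]
    i <- match(key, keys)
    if (is.na(i)) return(NA_character_)
    vals <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (i > length(vals)) NA_character_ else vals[[i]]
  }, format, sample, USE.NAMES = FALSE)
}

vcf_header <- function(reference = NULL, extra_info = character(0),
                       sample = "SAMPLE", source = "svforge") {
  h <- c("##fileformat=VCFv4.2",
         paste0("##source=", source))
  if (!is.null(reference)) {
    h <- c(h, sprintf("##contig=<ID=%s,length=%d>", names(reference),
                      nchar(reference)))
  }
  h <- c(h,
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End of the reference-consumed interval">',
    extra_info,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  h
}

write_vcf_lines <- function(header, records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(records)) {
    ord <- order(records$chrom, records$pos)
    rec <- records[ord, ]
    writeLines(paste(rec$chrom, rec$pos, rec$id, rec$ref, rec$alt, rec$qual,
                     rec$filter, rec$info, rec$format, rec$sample,
                     sep = "\t"), con)
  }
  invisible(path)
}
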