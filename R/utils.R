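#' @import methods
#' @importFrom stats runif rbinom rnorm setNames uniroot qlnorm plnorm pchisq
#' @importFrom utils read.delim write.table head tail
NULL

BASES <- c("A", "C", "G", "T")

SV_TYPES <- c("DEL", "INS", "DUP", "INVDUP", "INV", "TRA", "CSUB")
GENOTYPES <- c("HET_H1", "HET_H2", "HOM")

#' Derive a reproducible sub-seed from a master seed and a stage tag
#'
#' Each pipeline stage (SV placement, read simulation per chromosome or
#' haplotype, pseudo-caller perturbation, ...) draws from its own stream so
#' stages can be rerun independently and results do not depend on execution
#' order. The derivation is a fixed integer hash kept below 2^31.
#'
#' @param seed master integer seed
#' @param tag character stage label
#' @return an integer seed
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

## run `expr` under a local RNG state seeded with `seed`; the caller's RNG
## stream is restored afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Encode A/C/G/T as integers 0..3; anything else becomes NA.
dna_to_int <- function(x) {
  codes <- rep(NA_integer_, 128)
  codes[utf8ToInt("A") + 1L] <- 0L
  codes[utf8ToInt("C") + 1L] <- 1L
  codes[utf8ToInt("G") + 1L] <- 2L
  codes[utf8ToInt("T") + 1L] <- 3L
  codes[utf8ToInt(x) + 1L]
}

int_to_dna <- function(v) {
  intToUtf8(utf8ToInt("ACGT")[v + 1L])
}

## Reverse complement of a plain character string (uppercase ACGTN).
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## All 64 3-mers in fixed lexicographic order: index = 16*a + 4*b + c + 1.
all_kmers3 <- function() {
  g <- expand.grid(c = BASES, b = BASES, a = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$a, g$b, g$c)
}

## 3-mer index (1..64) of each interior position of an integer-encoded
## sequence; positions 1 and n get NA (no full context).
kmer_index <- function(ints) {
  n <- length(ints)
  if (n < 3L) return(rep(NA_integer_, n))
  idx <- rep(NA_integer_, n)
  idx[2:(n - 1L)] <- 16L * ints[1:(n - 2L)] + 4L * ints[2:(n - 1L)] +
    ints[3:n] + 1L
  idx
}

## Sample n random bases as an integer vector, optionally GC-biased.
sample_bases_int <- function(n, gc = 0.5) {
  if (n == 0L) return(integer(0))
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(0:3, n, replace = TRUE, prob = p)
}

## Likelihood-ratio (G) goodness-of-fit test of observed counts against
## expected probabilities. Returns the p-value; cells with zero expected
## probability must have zero counts.
g_test <- function(observed, prob) {
  stopifnot(length(observed) == length(prob))
  keep <- prob > 0
  if (any(observed[!keep] > 0)) return(0)
  o <- observed[keep]
  e <- sum(o) * prob[keep] / sum(prob[keep])
  nz <- o > 0
  g <- 2 * sum(o[nz] * log(o[nz] / e[nz]))
  df <- sum(keep) - 1L
  if (df < 1L) return(1)
  stats::pchisq(g, df = df, lower.tail = FALSE)
}

## Write a named list of character sequences as FASTA (70-column lines).
write_fasta <- function(seqs, path) {
  dna <- Biostrings::DNAStringSet(unlist(seqs))
  names(dna) <- names(seqs)
  Biostrings::writeXStringSet(dna, path, width = 70L)
  invisible(path)
}

## Read FASTA into a named character vector (uppercase).
read_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(dna))
  names(out) <- sub("\\s.*$", "", names(dna))
  out
}

## Coerce a sequence set argument (named character vector, list, or
## DNAStringSet) to a named character vector.
as_seq_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    out <- toupper(as.character(x))
    names(out) <- names(x)
    return(out)
  }
  if (is.list(x)) x <- unlist(x)
  stopifnot(is.character(x))
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("sequence sets must be named by chromosome")
  }
  toupper(x)
}
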