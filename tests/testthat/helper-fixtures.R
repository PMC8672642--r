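## Shared fixture builders; everything is generated in code at test time.

toy_ref <- function(seed = 101L, n_chroms = 2L, length = 100000L) {
  make_toy_genome(n_chroms, length, gc = 0.5, seed = seed)
}

## a small validated truth set of the five main SV types
toy_truth <- function(genome, seed = 11L, counts = c(DEL = 20, INS = 20,
                                                     DUP = 5, INV = 5,
                                                     CSUB = 5)) {
  cfg <- sv_sim_config(counts, length_range = list(default = c(50, 1000)),
                       seed = seed)
  generate_random_svs(cfg, genome)
}

## call-record row(s) in the shape read_caller_vcf() returns
call_row <- function(pos, length = 500L, caller = "x", chrom = "chr1",
                     sv_type = "DEL", genotype = "hom", support = 10L,
                     filter = "PASS") {
  data.frame(caller = caller, chrom = chrom, pos = as.integer(pos),
             length = as.integer(length), sv_type = sv_type,
             genotype = genotype, support = as.integer(support),
             filter = filter, stringsAsFactors = FALSE)
}

## truth events from bare fields, toy-validated
truth_row <- function(start, length = 500L, chrom = "chr1", sv_type = "DEL",
                      genotype = "HOM", inserted_seq = NULL) {
  df <- data.frame(chrom = chrom, start = as.integer(start),
                   sv_type = sv_type, length = as.integer(length),
                   stringsAsFactors = FALSE)
  if (!is.null(inserted_seq)) df$inserted_seq <- inserted_seq
  sv_events(df, toy = TRUE)
}
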