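# Small builders shared across test files. Everything is generated in code;
# no fixture files.

toy_loci <- function(n) {
  data.frame(chrom = "1", pos = seq_len(n) * 100L,
             ref = rep_len(c("A", "C", "G", "T"), n),
             alt = rep_len(c("G", "T", "A", "C"), n),
             stringsAsFactors = FALSE)
}

# dense integer matrices in, AlleleCounts out
toy_counts <- function(ref, alt, barcodes = NULL) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  if (is.null(barcodes)) barcodes <- sprintf("BC%03d", seq_len(ncol(ref)))
  allele_counts(ref, alt, barcodes, toy_loci(nrow(ref)))
}

# moderate two-genotype mixture used by several suites (cached per session)
small_mixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_loci = 600, n_majority_cells = 970,
                        n_minority_cells = 30, seed = 42)
      cache <<- c(simulate_mixture(cfg), list(config = cfg))
    }
    cache
  }
})
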