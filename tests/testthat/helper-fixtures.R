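# Small in-code fixtures shared across test files.

# tiny deterministic abundance table
tiny_table <- function() {
  m <- matrix(c(5, 0, 3,
                2, 4, 3,
                1, 1, 8,
                6, 2, 2), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  abundance_table(m)
}

tiny_metadata <- function() {
  sample_metadata(paste0("s", 1:4), c("A", "A", "B", "B"), c(1, 2, 1, 2))
}

# random counts table with given dims and seed
random_table <- function(n_samples, n_taxa, seed, depth = 1000) {
  m <- endocore:::with_seed(seed, {
    t(sapply(seq_len(n_samples), function(i) {
      stats::rmultinom(1, depth, stats::rlnorm(n_taxa, sdlog = 1))[, 1]
    }))
  })
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_samples)),
                      sprintf("t%02d", seq_len(n_taxa)))
  abundance_table(m)
}
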