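# Shared fixtures built in code (the deliverable contains no binary data).

# Small, fast synthetic-study configuration for unit tests; the acceptance
# tests use the package defaults.
tiny_config <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(n_chromosomes = 2, chrom_length = 3e5, n_oris = 150,
         n_informative_marks = 3, n_decoy_marks = 7,
         n_motifs = 2, n_loops = 80, negatives_per_gap = 4,
         seed = seed),
    list(...))
  do.call(synth_config, args)
}

# FeatureMatrix straight from a matrix, bypassing genomic encoding, for
# model-level tests.
make_fm <- function(X, labels, block = "epi") {
  colnames(X) <- paste0(block, ":f", sprintf("%02d", seq_len(ncol(X))))
  samples <- data.frame(chrom = "chr1",
                        start = seq_len(nrow(X)) * 1000L,
                        end = seq_len(nrow(X)) * 1000L + 500L)
  blocks <- list(X)
  names(blocks) <- block
  assemble_features(samples, labels, blocks)
}

# Bernoulli-feature matrix with a planted signal: the first n_inf columns
# fire with rate p_pos on positives and p_neg on negatives; the rest are
# rate p_neg everywhere.
planted_matrix <- function(n = 400, n_inf = 5, n_dec = 45,
                           p_pos = 0.8, p_neg = 0.2, seed = 1) {
  withr::with_seed(seed, {
    labels <- rep(c(1L, 0L), each = n / 2)
    p <- outer(labels, c(rep(1, n_inf), rep(0, n_dec))) * (p_pos - p_neg) + p_neg
    X <- matrix(as.numeric(runif(n * (n_inf + n_dec)) < p), n, n_inf + n_dec)
    list(X = X, labels = labels)
  })
}
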