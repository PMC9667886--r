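# Independent oracles: deliberately naive implementations used to verify
# the production code paths. They share no code with the package internals.

# Base-by-base enumeration of the covered fraction of one region.
oracle_overlap_ratio <- function(region, intervals) {
  bases <- seq(region$start, region$end - 1L)
  covered <- rep(FALSE, length(bases))
  for (i in seq_len(nrow(intervals))) {
    if (intervals$chrom[i] != region$chrom) next
    covered <- covered | (bases >= intervals$start[i] & bases < intervals$end[i])
  }
  sum(covered) / length(bases)
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Exhaustive both-strand window scoring using only relative_score().
oracle_count_occurrences <- function(pm, seqstr, threshold) {
  L <- motif_width(pm)
  n <- nchar(seqstr)
  if (n < L) return(0L)
  count <- 0L
  for (strand_seq in c(seqstr, oracle_revcomp(seqstr))) {
    for (i in seq_len(n - L + 1L)) {
      s <- relative_score(pm, substr(strand_seq, i, i + L - 1L))
      if (!is.na(s) && s >= threshold) count <- count + 1L
    }
  }
  count
}

# All-pairs Mann-Whitney probability.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Random position matrix with Poisson-ish counts (at least one positive
# count per column).
oracle_random_pm <- function(id, width) {
  counts <- matrix(rpois(4 * width, lambda = 3), 4, width)
  zero <- colSums(counts) == 0
  counts[1, zero] <- 1
  position_matrix(id, counts)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
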