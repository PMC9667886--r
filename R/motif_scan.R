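# PWM construction from count matrices and occurrence counting at a minimum
# relative matching score, on both strands.
#
# Scoring convention: a window of length L scores
#   S = sum_j log((count[b_j,j] + pc) / (colsum_j + 4 pc)) - log(background[b_j])
# and is reported as the relative score (S - Smin) / (Smax - Smin), where
# Smax/Smin are the column-wise best/worst attainable sums. The "minimum
# matching score of 80%" threshold operates on this 0-1 scale, which is the
# standard PWM-matching convention (absolute log-odds thresholds are not
# comparable across motifs). Windows containing non-ACGT characters are
# skipped silently but tallied in the scan report.

.BASES <- c("A", "C", "G", "T")

#' Construct a PositionMatrix (motif count matrix with scoring form)
#'
#' @param motif_id Identifier string (e.g. a JASPAR matrix ID).
#' @param counts 4 x L non-negative matrix, rows in A, C, G, T order.
#' @param pseudocount Small positive number added to every count cell before
#'   normalisation (default 0.01).
#' @param background Vector of 4 background base probabilities summing to 1
#'   (default uniform).
#' @return An object of class `PositionMatrix` carrying the counts, the
#'   derived log-odds score matrix, and the attainable score range.
#' @export
position_matrix <- function(motif_id, counts, pseudocount = 0.01,
                            background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 1L) stop("motif width must be >= 1")
  if (any(counts < 0)) stop("negative count in motif ", motif_id)
  if (pseudocount <= 0) stop("pseudocount must be positive")
  background <- as.numeric(background)
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-8 ||
      any(background <= 0)) {
    stop("background must be 4 positive probabilities summing to 1")
  }
  rownames(counts) <- .BASES
  colsums <- colSums(counts)
  p <- sweep(counts + pseudocount, 2, colsums + 4 * pseudocount, "/")
  lo <- log(p) - log(background)
  obj <- list(motif_id = motif_id, counts = counts,
              pseudocount = pseudocount,
              background = setNames(background, .BASES),
              log_odds = lo,
              smax = sum(apply(lo, 2, max)),
              smin = sum(apply(lo, 2, min)),
              width = ncol(counts))
  class(obj) <- "PositionMatrix"
  obj
}

#' @export
print.PositionMatrix <- function(x, ...) {
  cat(sprintf("PositionMatrix '%s': width %d, consensus %s\n",
              x$motif_id, x$width, consensus(x)))
  invisible(x)
}

#' Motif width (number of columns)
#' @param pm A `PositionMatrix`.
#' @return Integer width.
#' @export
motif_width <- function(pm) pm$width

#' Consensus sequence (column-wise maximal base; ties take the first of
#' A, C, G, T)
#' @param pm A `PositionMatrix`.
#' @return Consensus DNA string.
#' @export
consensus <- function(pm) {
  paste(.BASES[apply(pm$counts, 2, which.max)], collapse = "")
}

#' Encode a DNA string as integer base codes
#'
#' A=1, C=2, G=3, T=4; any other character (N, ambiguity codes) becomes NA,
#' which propagates to window scores and makes the scanner skip the window.
#' @param s DNA string.
#' @return Integer vector of codes.
#' @export
encode_dna <- function(s) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1]], .BASES)
}

#' Reverse-complement integer base codes
#' @noRd
.revcomp_codes <- function(codes) rev(5L - codes)

#' Raw window scores of a motif along encoded sequence
#' @noRd
.window_scores <- function(pm, codes) {
  L <- pm$width
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  lo <- pm$log_odds
  for (j in seq_len(L)) {
    s <- s + lo[codes[j:(j + n - 1L)] + 4L * (j - 1L)]
  }
  s
}

#' Relative matching score of one window
#'
#' `(S - Smin) / (Smax - Smin)` where Smax and Smin are the best and worst
#' attainable log-odds sums of the matrix, so the consensus scores 1 and the
#' column-wise worst window scores 0.
#'
#' @param pm A `PositionMatrix`.
#' @param window DNA string of exactly the motif width.
#' @return Fraction in `[0, 1]`, or `NA` if the window contains a non-ACGT
#'   character (such windows are undefined and skipped by the scanner).
#' @export
relative_score <- function(pm, window) {
  codes <- encode_dna(window)
  if (length(codes) != pm$width) {
    stop("window length ", length(codes), " != motif width ", pm$width)
  }
  if (anyNA(codes)) return(NA_real_)
  rng <- pm$smax - pm$smin
  if (rng <= 0) return(1)
  (sum(pm$log_odds[codes + 4L * (seq_len(pm$width) - 1L)]) - pm$smin) / rng
}

#' Relative scores of all windows in an encoded sequence
#' @noRd
.relative_scores <- function(pm, codes) {
  s <- .window_scores(pm, codes)
  rng <- pm$smax - pm$smin
  if (rng <= 0) return(ifelse(is.na(s), NA_real_, 1))
  (s - pm$smin) / rng
}

#' Count motif occurrences in a region, both strands
#'
#' Counts windows fully inside the region, on the forward strand and on the
#' reverse complement (scanned with the same matrix), whose relative score
#' meets the threshold. Overlapping hits all count; a palindromic-consensus
#' window matching on both strands counts twice. A region shorter than the
#' motif yields 0.
#'
#' @param pm A `PositionMatrix`.
#' @param region Single-row interval data frame (chrom/start/end).
#' @param genome Named character vector of sequences (see [read_fasta()]).
#' @param threshold Minimum relative matching score in `(0, 1]`
#'   (default 0.8, the conventional cutoff).
#' @return Non-negative integer count.
#' @export
count_occurrences <- function(pm, region, genome, threshold = 0.8) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  seq <- genome_subseq(genome, region$chrom, region$start, region$end)
  .count_codes(pm, encode_dna(seq), threshold)
}

#' @noRd
.count_codes <- function(pm, codes, threshold) {
  fwd <- .relative_scores(pm, codes)
  rev <- .relative_scores(pm, .revcomp_codes(codes))
  sum(fwd >= threshold, na.rm = TRUE) + sum(rev >= threshold, na.rm = TRUE)
}

#' Locate motif hits in a region, both strands
#'
#' Like [count_occurrences()] but returning hit locations. Reverse-strand
#' hit coordinates refer to the forward genome (0-based half-open).
#'
#' @inheritParams count_occurrences
#' @return Data frame with columns `motif_id`, `chrom`, `start`, `end`,
#'   `strand`, `relative_score`, plus attribute `n_skipped_windows` (windows
#'   containing non-ACGT characters, per strand scan).
#' @export
motif_hits <- function(pm, region, genome, threshold = 0.8) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  seq <- genome_subseq(genome, region$chrom, region$start, region$end)
  codes <- encode_dna(seq)
  L <- pm$width
  fwd <- .relative_scores(pm, codes)
  rev <- .relative_scores(pm, .revcomp_codes(codes))
  n <- length(codes)
  fi <- which(!is.na(fwd) & fwd >= threshold)
  ri <- which(!is.na(rev) & rev >= threshold)
  # window i on the reverse-complemented sequence covers forward positions
  # [n - i - L + 1, n - i + 1) (0-based within the region)
  out <- data.frame(
    motif_id = pm$motif_id,
    chrom = region$chrom,
    start = region$start + c(fi - 1L, n - ri - L + 1L),
    end = region$start + c(fi + L - 1L, n - ri + 1L),
    strand = rep(c("+", "-"), c(length(fi), length(ri))),
    relative_score = c(fwd[fi], rev[ri]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped_windows") <- sum(is.na(fwd)) + sum(is.na(rev))
  out
}

#' Export motif hits as BED6
#'
#' Score column carries the relative score scaled to 0-1000.
#' @param hits Data frame from [motif_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_hits_bed <- function(hits, path) {
  df <- data.frame(chrom = hits$chrom, start = hits$start, end = hits$end,
                   name = hits$motif_id,
                   score = as.integer(round(1000 * hits$relative_score)),
                   strand = hits$strand, stringsAsFactors = FALSE)
  write_bed(df, path)
}
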