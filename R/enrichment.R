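# Descriptive analyses around the classifier: colocalization frequencies
# with a two-sample test on per-region indicators, motif odds-ratio
# enrichment from 2x2 tables, anchor-centred enrichment profiles, and
# maximum-likelihood gamma fits to ORI length and spacing distributions.

#' Colocalization frequency of a mark with a region set
#'
#' Fraction of regions overlapping at least one interval of the track.
#' @param regions Interval data frame (non-empty).
#' @param track A `TrackSet` or interval data frame.
#' @return Fraction in `[0, 1]`.
#' @export
colocalization_frequency <- function(regions, track) {
  .check_intervals(regions, "regions", allow_empty = FALSE)
  tdf <- if (.is_track(track)) track$intervals else track
  if (nrow(tdf) == 0) return(0)
  coverage_fraction_of_regions(regions, tdf)
}

#' Compare colocalization between two region sets
#'
#' Tests whether a mark is present more often at one region set (e.g.
#' ORIs) than another (non-ORIs). The per-region presence/absence
#' indicators feed a Welch two-sample t-test, which makes the test
#' well-defined at region granularity; a two-proportion z-test is the
#' alternative.
#'
#' @param regions_a,regions_b Interval data frames (e.g. ORIs, non-ORIs).
#' @param track A `TrackSet` or interval data frame.
#' @param method `"t"` (Welch, default) or `"z"` (two-proportion z-test).
#' @return List with `freq_a`, `freq_b`, `p_value`, `method`.
#' @export
colocalization_compare <- function(regions_a, regions_b, track,
                                   method = c("t", "z")) {
  method <- match.arg(method)
  .check_intervals(regions_a, "regions_a", allow_empty = FALSE)
  .check_intervals(regions_b, "regions_b", allow_empty = FALSE)
  tdf <- if (.is_track(track)) track$intervals else track
  if (nrow(tdf) == 0) {
    warning("empty track: frequencies are 0 and the test is undefined; p = 1")
    return(list(freq_a = 0, freq_b = 0, p_value = 1, method = method))
  }
  ind_a <- as.numeric(suppressWarnings(
    GenomicRanges::countOverlaps(.as_gr(regions_a), .as_gr(tdf))) > 0)
  ind_b <- as.numeric(suppressWarnings(
    GenomicRanges::countOverlaps(.as_gr(regions_b), .as_gr(tdf))) > 0)
  fa <- mean(ind_a)
  fb <- mean(ind_b)
  p <- if (method == "t") {
    if (stats::var(ind_a) == 0 && stats::var(ind_b) == 0) {
      # degenerate indicators: identical proportions are indistinguishable,
      # different constant proportions are maximally distinguishable
      if (fa == fb) 1 else 0
    } else {
      t.test(ind_a, ind_b)$p.value
    }
  } else {
    n1 <- length(ind_a); n2 <- length(ind_b)
    pp <- (sum(ind_a) + sum(ind_b)) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    if (se == 0) 1 else 2 * pnorm(-abs((fa - fb) / se))
  }
  list(freq_a = fa, freq_b = fb, p_value = p, method = method)
}

#' Per-mark colocalization enrichment table
#'
#' Convenience wrapper applying [colocalization_compare()] to each track.
#' @param regions_pos,regions_neg Interval data frames (ORIs / non-ORIs).
#' @param tracks List of `TrackSet` objects.
#' @param method Passed to [colocalization_compare()].
#' @return Data frame (mark, freq_ori, freq_non_ori, p_value).
#' @export
enrichment_table <- function(regions_pos, regions_neg, tracks,
                             method = "t") {
  rows <- lapply(tracks, function(tr) {
    cmp <- colocalization_compare(regions_pos, regions_neg, tr, method)
    data.frame(mark = tr$name, freq_ori = cmp$freq_a,
               freq_non_ori = cmp$freq_b, p_value = cmp$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Motif enrichment odds ratio from a 2x2 table
#'
#' With `a` = positives with the motif, `b` = positives without, `c` =
#' negatives with, `d` = negatives without: `OR = (a d) / (b c)`. If any
#' cell is zero the Haldane-Anscombe correction (+0.5 to every cell) is
#' applied and flagged. Also reports the percentage of positive loci
#' carrying the motif.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return List with `odds_ratio`, `percentage` (`100 a / (a + b)`), and
#'   `haldane_corrected` flag.
#' @export
motif_odds_ratio <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  if (a + b == 0) stop("no positive loci (a + b = 0)")
  corrected <- any(c(a, b, c, d) == 0)
  cells <- c(a, b, c, d) + if (corrected) 0.5 else 0
  list(odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
       percentage = 100 * a / (a + b),
       haldane_corrected = corrected)
}

#' Anchor-centred enrichment profile
#'
#' Bins the window around each anchor midpoint and reports, per bin offset,
#' the mean base-coverage fraction of the track — the meta-profile used to
#' compare a mark's density at regions versus their flanks. With
#' `normalize = TRUE` values are divided by the mean of the outermost 10%
#' of bins (flank normalisation), so a flat profile sits near 1.
#'
#' @param anchors Interval data frame; the profile is centred on each
#'   interval's midpoint.
#' @param track A `TrackSet` or interval data frame.
#' @param half_window Half-width of the profiled window in bp
#'   (default 3000).
#' @param bin_size Bin width in bp (default 50); the profile has
#'   `2 * (half_window / bin_size) + 1` bins centred at offset 0.
#' @param normalize Divide by the mean of the outermost 10% of bins
#'   (default `TRUE`).
#' @param chrom_sizes Optional named vector of contig lengths; anchors
#'   whose midpoint lies closer than `half_window` to a contig edge are
#'   skipped (always skipped at the left edge), with the count reported.
#' @return An object of class `EnrichmentProfile`: `offsets` (bin centres,
#'   bp), `values`, `half_window`, `bin_size`, `n_anchors`, `n_skipped`,
#'   `normalized`.
#' @export
anchor_profile <- function(anchors, track, half_window = 3000, bin_size = 50,
                           normalize = TRUE, chrom_sizes = NULL) {
  .check_intervals(anchors, "anchors", allow_empty = FALSE)
  if (half_window %% bin_size != 0) {
    stop("half_window must be a multiple of bin_size")
  }
  mid <- floor((anchors$start + anchors$end) / 2)
  half_bin <- bin_size / 2
  keep <- mid - half_window - half_bin >= 0
  if (!is.null(chrom_sizes)) {
    sizes <- chrom_sizes[anchors$chrom]
    keep <- keep & !is.na(sizes) & (mid + half_window + half_bin <= sizes)
  }
  n_skipped <- sum(!keep)
  if (!any(keep)) stop("all anchors lie closer than half_window to a contig edge")
  mid <- mid[keep]
  chrom <- anchors$chrom[keep]
  centers <- seq(-half_window, half_window, by = bin_size)
  nb <- length(centers)
  bins <- data.frame(
    chrom = rep(chrom, each = nb),
    start = rep(mid, each = nb) + rep(centers, length(mid)) - half_bin,
    end = rep(mid, each = nb) + rep(centers, length(mid)) + half_bin
  )
  cov <- region_coverage(bins, track) / bin_size
  values <- colMeans(matrix(cov, ncol = nb, byrow = TRUE))
  if (normalize) {
    k <- max(1L, floor(0.05 * nb))  # outermost 10% = k bins per side
    flank <- mean(values[c(seq_len(k), nb - seq_len(k) + 1L)])
    if (flank > 0) values <- values / flank
  }
  obj <- list(offsets = centers, values = values, half_window = half_window,
              bin_size = bin_size, n_anchors = length(mid),
              n_skipped = n_skipped, normalized = normalize)
  class(obj) <- "EnrichmentProfile"
  obj
}

#' @export
print.EnrichmentProfile <- function(x, ...) {
  cat(sprintf(
    "EnrichmentProfile: %d bins of %d bp over +/-%d bp, %d anchors (%d skipped)%s\n",
    length(x$offsets), x$bin_size, x$half_window, x$n_anchors, x$n_skipped,
    if (x$normalized) ", flank-normalized" else ""))
  invisible(x)
}

#' Maximum-likelihood gamma fit
#'
#' Fits shape and scale by MLE: the shape solves
#' `log(k) - digamma(k) = log(mean(x)) - mean(log(x))` (Newton iterations
#' with a generalised-method-of-moments start), and the scale is
#' `mean(x) / shape`, so the fitted mean equals the sample mean exactly.
#' ORI lengths and inter-ORI distances are both well described by this
#' family.
#'
#' @param x Positive values (n >= 30).
#' @return List with `shape`, `scale`, `loglik`.
#' @export
fit_gamma <- function(x) {
  if (length(x) < 30) stop("need at least 30 observations")
  if (any(x <= 0)) stop("all values must be positive")
  if (stats::var(x) == 0) stop("zero variance: degenerate sample")
  m <- mean(x)
  s <- log(m) - mean(log(x))  # > 0 by Jensen unless degenerate
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:50) {
    step <- (log(k) - digamma(k) - s) / (1 / k - trigamma(k))
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-10 * k) {
      k <- k_new
      break
    }
    k <- k_new
  }
  scale <- m / k
  list(shape = k, scale = scale,
       loglik = sum(dgamma(x, shape = k, scale = scale, log = TRUE)))
}
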