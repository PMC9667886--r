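# Interval arithmetic underlying every feature and enrichment computation.
# Semantics fixed here once: the overlap ratio is the base-coverage of the
# candidate region (covered bases / region length), with the track merged
# first so double-covered bases are counted once. Coordinates are 0-based
# half-open throughout; IRanges/GenomicRanges do the heavy lifting.

#' Merge (union) an interval set
#'
#' @param df Interval data frame (chrom/start/end, 0-based half-open).
#' @return Sorted data frame of disjoint merged intervals.
#' @export
merge_intervals <- function(df) {
  .check_intervals(df)
  if (nrow(df) == 0) return(.empty_intervals())
  red <- GenomicRanges::reduce(.as_gr(df))
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red) - 1L,
             end = GenomicRanges::end(red),
             stringsAsFactors = FALSE)
}

#' Bases of each region covered by a track
#'
#' Vectorised workhorse behind [overlap_ratio()] and the epigenomic feature
#' block: for every region, the number of its bases covered by the union of
#' the track's intervals.
#'
#' @param regions Interval data frame (one row per candidate region).
#' @param track A `TrackSet` or interval data frame.
#' @return Integer vector of covered base counts, one per region.
#' @export
region_coverage <- function(regions, track) {
  .check_intervals(regions, "regions")
  tdf <- if (.is_track(track)) track$intervals else track
  .check_intervals(tdf, "track")
  covered <- integer(nrow(regions))
  if (nrow(regions) == 0 || nrow(tdf) == 0) return(covered)
  q <- .as_gr(regions)
  red <- GenomicRanges::reduce(.as_gr(tdf))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, red))
  if (length(hits) > 0) {
    pieces <- IRanges::pintersect(q[S4Vectors::queryHits(hits)],
                                  red[S4Vectors::subjectHits(hits)])
    w <- tapply(GenomicRanges::width(pieces), S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(w))] <- as.integer(w)
  }
  covered
}

#' Overlap ratio of a track with one region
#'
#' Fraction of the region's bases covered by the union of the track's
#' intervals — the per-sample feature value of the epigenomic block. A
#' region with no track intervals on its chromosome scores 0.
#'
#' @param region Single-row interval data frame (or list with chrom, start,
#'   end).
#' @param track A `TrackSet` or interval data frame.
#' @return Fraction in `[0, 1]`.
#' @export
overlap_ratio <- function(region, track) {
  region <- as.data.frame(region[c("chrom", "start", "end")])
  if (nrow(region) != 1L) stop("overlap_ratio expects a single region")
  len <- region$end - region$start
  if (len <= 0) stop("region has non-positive length")
  region_coverage(region, track) / len
}

#' Fraction of regions touched by a track
#'
#' The region-set counterpart of [overlap_ratio()]: the fraction of regions
#' that share at least one base with the track.
#'
#' @param regions Interval data frame (must be non-empty).
#' @param track A `TrackSet` or interval data frame.
#' @return Fraction in `[0, 1]`.
#' @export
coverage_fraction_of_regions <- function(regions, track) {
  .check_intervals(regions, "regions")
  if (nrow(regions) == 0) stop("empty region set")
  tdf <- if (.is_track(track)) track$intervals else track
  if (nrow(tdf) == 0) return(0)
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(.as_gr(regions), .as_gr(tdf))
  )
  mean(hits > 0)
}

#' Gaps between adjacent regions on each chromosome
#'
#' Regions are merged first, so overlapping input is handled; one gap is
#' emitted per adjacent same-chromosome pair, as `[left.end, right.start)`.
#' Zero-length gaps (abutting regions) are omitted.
#'
#' @param regions Interval data frame.
#' @return Data frame with columns `chrom`, `start`, `end` (the gap, 0-based
#'   half-open) and `left_start`, `left_end`, `right_start`, `right_end`
#'   (the flanking merged regions).
#' @export
gaps_between_adjacent <- function(regions) {
  m <- merge_intervals(regions)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(m) < 2) return(empty)
  out <- lapply(split(m, m$chrom), function(ch) {
    if (nrow(ch) < 2) return(NULL)
    left <- ch[-nrow(ch), ]
    right <- ch[-1, ]
    g <- data.frame(chrom = left$chrom, start = left$end, end = right$start,
                    left_start = left$start, left_end = left$end,
                    right_start = right$start, right_end = right$end,
                    stringsAsFactors = FALSE)
    g[g$end > g$start, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0) return(empty)
  rownames(out) <- NULL
  .sort_intervals(out)
}
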