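# Benchmark dataset construction: positives are the ORI intervals as given;
# negatives are fragments of 800-1000 bp sampled from inter-ORI gaps longer
# than 10 kb, so they are far from any origin. Splits are stratified by
# label: 30% held out as the independent set, the remainder divided 8:2
# into train and tune sets.

#' Candidate negative slots in qualifying inter-ORI gaps
#'
#' Deterministic slot geometry shared by [build_negatives()] and the
#' synthetic-mark generator: for every merged same-chromosome ORI gap
#' strictly longer than `gap_min`, up to `per_gap` evenly spaced slot
#' centres, spaced at least `max(len_range)` apart so fragments drawn
#' around them cannot overlap.
#'
#' @param oris Interval data frame of ORIs.
#' @param gap_min Minimum gap length in bp, strict (default 10000).
#' @param len_range Fragment length range in bp (default `c(800, 1000)`).
#' @param per_gap Maximum number of fragments per qualifying gap.
#' @return Data frame with columns `chrom`, `center`.
#' @export
negative_slots <- function(oris, gap_min = 10000, len_range = c(800, 1000),
                           per_gap = 1) {
  gaps <- gaps_between_adjacent(oris)
  gaps <- gaps[(gaps$end - gaps$start) > gap_min, , drop = FALSE]
  if (nrow(gaps) == 0) {
    return(data.frame(chrom = character(), center = numeric()))
  }
  max_len <- max(len_range)
  out <- lapply(seq_len(nrow(gaps)), function(i) {
    glen <- gaps$end[i] - gaps$start[i]
    m <- min(per_gap, max(1L, floor(glen / max_len) - 1L))
    centers <- gaps$start[i] + round(seq_len(m) * glen / (m + 1))
    data.frame(chrom = gaps$chrom[i], center = centers,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sample non-ORI (negative) fragments from long inter-ORI gaps
#'
#' For each adjacent same-chromosome ORI gap strictly longer than
#' `gap_min`, emits fragments whose length is drawn uniformly from
#' `len_range` (seeded) around deterministic slot centres; with the default
#' `per_gap = 1` a single fragment centred in the gap. Fragments never
#' overlap any ORI or each other.
#'
#' @param oris Interval data frame of ORIs (merged internally).
#' @param gap_min Gap length threshold in bp, strict (default 10000).
#' @param len_range Fragment length range in bp (default `c(800, 1000)`).
#' @param per_gap Fragments per qualifying gap (default 1; larger values
#'   sample gaps more densely to reach a target class ratio).
#' @param seed Integer seed for the fragment-length draws.
#' @return Interval data frame of negative fragments, sorted.
#' @export
build_negatives <- function(oris, gap_min = 10000, len_range = c(800, 1000),
                            per_gap = 1, seed = 1) {
  .check_intervals(oris, "oris")
  if (nrow(oris) == 0) stop("need >= 2 ORIs on some chromosome to define gaps")
  merged <- merge_intervals(oris)
  slots <- negative_slots(merged, gap_min, len_range, per_gap)
  if (nrow(slots) == 0) {
    return(.empty_intervals())
  }
  .with_seed(seed, {
    len <- sample(seq(len_range[1], len_range[2]), nrow(slots), replace = TRUE)
    start <- as.integer(round(slots$center - len / 2))
    data.frame(chrom = slots$chrom, start = start, end = start + len,
               stringsAsFactors = FALSE) |> .sort_intervals()
  })
}

#' Construct a labelled benchmark dataset
#'
#' Positives are the (merged) ORI intervals; negatives come from
#' [build_negatives()]. With `ratio = 1` the larger class is subsampled
#' (seeded) to a balanced 1:1 dataset; `ratio = n` targets n negatives per
#' positive where the data allow.
#'
#' @inheritParams build_negatives
#' @param ratio Target negative:positive ratio (default 1; `NA` keeps all).
#' @return An object of class `LabeledDataset`: list with `positives`,
#'   `negatives` and a `provenance` record sufficient to reproduce it.
#' @export
build_dataset <- function(oris, gap_min = 10000, len_range = c(800, 1000),
                          per_gap = 1, ratio = 1, seed = 1) {
  positives <- merge_intervals(oris)
  negatives <- build_negatives(oris, gap_min, len_range, per_gap, seed = seed)
  if (!is.na(ratio)) {
    .with_seed(seed + 1L, {
      target_neg <- round(nrow(positives) * ratio)
      if (nrow(negatives) > target_neg) {
        negatives <- .sort_intervals(
          negatives[sample(nrow(negatives), target_neg), , drop = FALSE])
      } else if (nrow(negatives) < target_neg && ratio == 1) {
        positives <- .sort_intervals(
          positives[sample(nrow(positives), nrow(negatives)), , drop = FALSE])
      }
    })
  }
  obj <- list(positives = positives, negatives = negatives,
              provenance = list(gap_min = gap_min, len_range = len_range,
                                per_gap = per_gap, ratio = ratio, seed = seed))
  class(obj) <- "LabeledDataset"
  obj
}

#' @export
print.LabeledDataset <- function(x, ...) {
  cat(sprintf("LabeledDataset: %d positives, %d negatives\n",
              nrow(x$positives), nrow(x$negatives)))
  invisible(x)
}

#' All samples of a LabeledDataset with labels
#' @param ds A `LabeledDataset`.
#' @return Data frame (chrom, start, end, label) with positives first.
#' @export
dataset_samples <- function(ds) {
  rbind(
    cbind(ds$positives[, c("chrom", "start", "end")], label = 1L),
    cbind(ds$negatives[, c("chrom", "start", "end")], label = 0L)
  )
}

#' Stratified train / tune / independent split
#'
#' Per class: `independent_frac` of the samples (rounded) go to the
#' independent set; the remainder is divided so that `tune_frac_of_train`
#' goes to the tune set and the rest to the train set. With the defaults
#' this is the 7:3 split followed by 8:2 within the training portion.
#'
#' @param ds A `LabeledDataset`.
#' @param independent_frac Fraction per class held out as the independent
#'   set (default 0.3).
#' @param tune_frac_of_train Fraction of the remainder used to test and
#'   tune (default 0.2).
#' @param seed Integer seed for the per-class shuffles.
#' @return An object of class `SplitPlan`: list of integer index vectors
#'   `train`, `tune`, `independent` into [dataset_samples()] row order,
#'   plus the fractions and seed.
#' @export
stratified_split <- function(ds, independent_frac = 0.3,
                             tune_frac_of_train = 0.2, seed = 1) {
  samples <- dataset_samples(ds)
  for (lab in c(0L, 1L)) {
    if (sum(samples$label == lab) < 5) {
      stop("class ", lab, " has fewer than 5 samples")
    }
  }
  train <- tune <- independent <- integer(0)
  .with_seed(seed, {
    for (lab in c(1L, 0L)) {
      idx <- which(samples$label == lab)
      idx <- idx[sample.int(length(idx))]
      n_ind <- round(independent_frac * length(idx))
      ind <- idx[seq_len(n_ind)]
      rest <- idx[-seq_len(n_ind)]
      if (n_ind == 0) rest <- idx
      n_tune <- round(tune_frac_of_train * length(rest))
      independent <- c(independent, ind)
      tune <- c(tune, rest[seq_len(n_tune)])
      train <- c(train, if (n_tune == 0) rest else rest[-seq_len(n_tune)])
    }
  })
  obj <- list(train = sort(train), tune = sort(tune),
              independent = sort(independent),
              independent_frac = independent_frac,
              tune_frac_of_train = tune_frac_of_train, seed = seed)
  class(obj) <- "SplitPlan"
  obj
}

#' @export
print.SplitPlan <- function(x, ...) {
  cat(sprintf("SplitPlan: train %d, tune %d, independent %d (seed %d)\n",
              length(x$train), length(x$tune), length(x$independent), x$seed))
  invisible(x)
}

#' Subsampled imbalanced datasets (positive folds vs all negatives)
#'
#' Divides the positives into `n_folds` disjoint, exhaustive folds and
#' pairs each fold with the whole negative set, producing datasets with an
#' (approximate) 1:`n_folds` class ratio for imbalance-robustness checks.
#'
#' @param ds A `LabeledDataset`.
#' @param n_folds Number of positive folds (default 5).
#' @param seed Optional seed to shuffle positives before folding; `NULL`
#'   folds in input order.
#' @return List of `n_folds` `LabeledDataset` objects.
#' @export
subsample_imbalanced <- function(ds, n_folds = 5, seed = NULL) {
  np <- nrow(ds$positives)
  if (np < n_folds) stop("need at least n_folds positives")
  ord <- seq_len(np)
  if (!is.null(seed)) ord <- .with_seed(seed, sample.int(np))
  fold_of <- rep(seq_len(n_folds), length.out = np)
  lapply(seq_len(n_folds), function(k) {
    pos <- ds$positives[ord[fold_of == k], , drop = FALSE]
    obj <- list(positives = .sort_intervals(pos), negatives = ds$negatives,
                provenance = c(ds$provenance, list(fold = k, n_folds = n_folds)))
    class(obj) <- "LabeledDataset"
    obj
  })
}

#' Partition annotation regions by ORI overlap
#'
#' Splits an annotation track (promoters, enhancers, ...) into the regions
#' that share at least one base with an ORI and those that do not — the two
#' classes of the annotation-anchored control datasets.
#'
#' @param oris Interval data frame of ORIs.
#' @param annotation A `TrackSet` or interval data frame of annotation
#'   regions.
#' @return List with `with_ori`, `without_ori` (interval data frames) and
#'   counts `n_with`, `n_without`.
#' @export
intersect_with_annotation <- function(oris, annotation) {
  adf <- if (.is_track(annotation)) annotation$intervals else annotation
  .check_intervals(adf, "annotation", allow_empty = FALSE)
  .check_intervals(oris, "oris", allow_empty = FALSE)
  hit <- suppressWarnings(
    GenomicRanges::countOverlaps(.as_gr(adf), .as_gr(oris))
  ) > 0
  list(with_ori = adf[hit, , drop = FALSE],
       without_ori = adf[!hit, , drop = FALSE],
       n_with = sum(hit), n_without = sum(!hit))
}
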