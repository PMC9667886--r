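# Assembly of the three feature blocks (epigenomic overlap ratios, motif
# occurrence counts, chromatin-loop features) into one labelled feature
# matrix. Column names are stable keys: "epi:<track>", "motif:<id>",
# "loop:<dataset>:abundance" / "loop:<dataset>:anchor_ratio", so importance
# tables and cross-cell-line intersections survive reordering.

#' Epigenomic feature block: overlap ratio per mark
#'
#' One column per track, holding [overlap_ratio()] of each sample region
#' with that mark's peaks. Column order follows track input order.
#'
#' @param samples Interval data frame of sample regions.
#' @param tracks List of `TrackSet` objects with unique names.
#' @return Numeric matrix (samples x tracks), values in `[0, 1]`, columns
#'   named `epi:<track>`.
#' @export
encode_epigenomic <- function(samples, tracks) {
  .check_intervals(samples, "samples")
  if (length(tracks) < 1) stop("need at least one track")
  nms <- vapply(tracks, function(t) t$name, character(1))
  if (anyDuplicated(nms)) {
    stop("duplicate track names: ", paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  len <- samples$end - samples$start
  X <- vapply(tracks, function(tr) region_coverage(samples, tr) / len,
              numeric(nrow(samples)))
  X <- matrix(X, nrow = nrow(samples),
              dimnames = list(NULL, paste0("epi:", nms)))
  X
}

#' Motif feature block: occurrence counts per motif
#'
#' One integer column per motif, holding the number of windows (both
#' strands) at or above the relative-score threshold within each sample
#' region. The raw count is the feature; `per_kb = TRUE` optionally divides
#' by region length in kb (positives and negatives differ in length, but
#' the raw count is the default to match the canonical encoding).
#'
#' @param samples Interval data frame of sample regions.
#' @param pms List of `PositionMatrix` objects with distinct IDs.
#' @param genome Named character vector of sequences.
#' @param threshold Minimum relative matching score (default 0.8).
#' @param per_kb Normalise counts per kilobase of region length
#'   (default `FALSE`).
#' @return Numeric matrix (samples x motifs), columns named `motif:<id>`.
#' @export
encode_motifs <- function(samples, pms, genome, threshold = 0.8,
                          per_kb = FALSE) {
  .check_intervals(samples, "samples")
  if (length(pms) < 1) stop("need at least one motif")
  ids <- vapply(pms, function(p) p$motif_id, character(1))
  if (anyDuplicated(ids)) {
    stop("motif_id collision: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  X <- matrix(0, nrow = nrow(samples), ncol = length(pms),
              dimnames = list(NULL, paste0("motif:", ids)))
  for (i in seq_len(nrow(samples))) {
    seq <- genome_subseq(genome, samples$chrom[i], samples$start[i],
                         samples$end[i])
    codes <- encode_dna(seq)
    rc <- .revcomp_codes(codes)
    for (k in seq_along(pms)) {
      pm <- pms[[k]]
      X[i, k] <- sum(.relative_scores(pm, codes) >= threshold, na.rm = TRUE) +
        sum(.relative_scores(pm, rc) >= threshold, na.rm = TRUE)
    }
  }
  if (per_kb) X <- X / ((samples$end - samples$start) / 1000)
  X
}

#' Chromatin-loop feature block: abundance and anchor overlap ratio
#'
#' Per loop dataset, two columns per sample: interaction abundance — the
#' number of loops in the dataset with at least one anchor overlapping the
#' sample region, each loop counted at most once — and the anchor overlap
#' ratio, [overlap_ratio()] of the sample against the union of the
#' dataset's anchors. `both_ends = TRUE` switches abundance to the stricter
#' reading in which both anchors of a loop must overlap the sample region.
#'
#' @param samples Interval data frame of sample regions.
#' @param loops Loop data frame (see [read_bedpe()]), possibly several
#'   datasets distinguished by the `dataset` column.
#' @param both_ends Require both anchors to overlap the sample for the
#'   abundance count (default `FALSE`).
#' @return Numeric matrix (samples x 2 * n datasets), columns named
#'   `loop:<dataset>:abundance` and `loop:<dataset>:anchor_ratio`.
#' @export
encode_loops <- function(samples, loops, both_ends = FALSE) {
  .check_intervals(samples, "samples")
  if (nrow(loops) < 1) stop("need at least one loop")
  if (any(!nzchar(loops$dataset)) || anyNA(loops$dataset)) {
    stop("unknown dataset tag: every loop must carry a non-empty dataset")
  }
  datasets <- unique(loops$dataset)
  q <- .as_gr(samples)
  cols <- list()
  for (ds in datasets) {
    sub <- loops[loops$dataset == ds, , drop = FALSE]
    a1 <- .as_gr(data.frame(chrom = sub$chrom1, start = sub$start1,
                            end = sub$end1))
    a2 <- .as_gr(data.frame(chrom = sub$chrom2, start = sub$start2,
                            end = sub$end2))
    h1 <- suppressWarnings(GenomicRanges::findOverlaps(q, a1))
    h2 <- suppressWarnings(GenomicRanges::findOverlaps(q, a2))
    p1 <- cbind(S4Vectors::queryHits(h1), S4Vectors::subjectHits(h1))
    p2 <- cbind(S4Vectors::queryHits(h2), S4Vectors::subjectHits(h2))
    abundance <- numeric(nrow(samples))
    pairs <- if (both_ends) {
      # loop counted only when both anchors overlap the sample
      m1 <- paste(p1[, 1], p1[, 2])
      m2 <- paste(p2[, 1], p2[, 2])
      p1[m1 %in% m2, , drop = FALSE]
    } else {
      unique(rbind(p1, p2))
    }
    if (nrow(pairs) > 0) {
      tab <- table(pairs[, 1])
      abundance[as.integer(names(tab))] <- as.integer(tab)
    }
    anchors <- rbind(
      data.frame(chrom = sub$chrom1, start = sub$start1, end = sub$end1),
      data.frame(chrom = sub$chrom2, start = sub$start2, end = sub$end2)
    )
    ratio <- region_coverage(samples, anchors) / (samples$end - samples$start)
    cols[[paste0("loop:", ds, ":abundance")]] <- abundance
    cols[[paste0("loop:", ds, ":anchor_ratio")]] <- ratio
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  X
}

#' Assemble feature blocks into a labelled FeatureMatrix
#'
#' @param samples Interval data frame of sample regions (row order shared by
#'   every block).
#' @param labels Vector of 1 (ORI) / 0 (non-ORI) labels, one per sample.
#' @param blocks Named list of numeric matrices (e.g. `epi`, `motif`,
#'   `loop`) with equal row counts.
#' @return An object of class `FeatureMatrix`: list with `samples`,
#'   `labels`, `X` (the column-bound matrix) and `blocks` (block name ->
#'   column names).
#' @export
assemble_features <- function(samples, labels, blocks) {
  .check_intervals(samples, "samples")
  if (length(labels) != nrow(samples)) stop("labels/sample row count mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  if (length(blocks) < 1) stop("need at least one block")
  nr <- vapply(blocks, nrow, integer(1))
  if (any(nr != nrow(samples))) {
    stop("row-count mismatch: blocks have rows ", paste(nr, collapse = ", "),
         " but there are ", nrow(samples), " samples")
  }
  X <- do.call(cbind, unname(blocks))
  if (anyDuplicated(colnames(X))) stop("duplicate feature column names")
  if (anyNA(X)) stop("missing values in feature matrix")
  obj <- list(samples = samples, labels = as.integer(labels), X = X,
              blocks = lapply(blocks, colnames))
  class(obj) <- "FeatureMatrix"
  obj
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  bl <- paste(sprintf("%s=%d", names(x$blocks), lengths(x$blocks)),
              collapse = ", ")
  cat(sprintf("FeatureMatrix: %d samples (%d ORI / %d non-ORI) x %d features (%s)\n",
              nrow(x$X), sum(x$labels == 1), sum(x$labels == 0), ncol(x$X), bl))
  invisible(x)
}

#' @export
dim.FeatureMatrix <- function(x) dim(x$X)

#' Restrict a FeatureMatrix to a subset of feature columns
#' @param fm A `FeatureMatrix`.
#' @param features Character vector of column names to keep.
#' @return A `FeatureMatrix` with the selected columns (block index pruned
#'   accordingly).
#' @export
subset_features <- function(fm, features) {
  miss <- setdiff(features, colnames(fm$X))
  if (length(miss)) stop("unknown features: ", paste(miss, collapse = ", "))
  fm$X <- fm$X[, features, drop = FALSE]
  fm$blocks <- lapply(fm$blocks, intersect, features)
  fm
}

#' Block retention of a feature subset
#'
#' For a selected feature subset (e.g. the optimum found by RFE), the
#' percentage of each original block that was retained.
#'
#' @param selected Character vector of selected feature names.
#' @param blocks Named list of block column names (as in
#'   `FeatureMatrix$blocks`), or a `FeatureMatrix`.
#' @return Data frame with columns `block`, `selected`, `total`,
#'   `percentage` (of the block retained, in percent).
#' @export
block_retention <- function(selected, blocks) {
  if (inherits(blocks, "FeatureMatrix")) blocks <- blocks$blocks
  data.frame(
    block = names(blocks),
    selected = vapply(blocks, function(b) length(intersect(selected, b)),
                      integer(1)),
    total = lengths(blocks),
    percentage = 100 * vapply(blocks, function(b)
      length(intersect(selected, b)) / length(b), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write a FeatureMatrix as TSV
#'
#' Layout: header row of feature names preceded by `chrom`, `start`, `end`,
#' `label`; one row per sample. Block membership is recoverable from the
#' `epi:` / `motif:` / `loop:` column-name prefixes.
#'
#' @param fm A `FeatureMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(fm, path) {
  df <- cbind(fm$samples[, c("chrom", "start", "end")],
              label = fm$labels,
              as.data.frame(fm$X, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FeatureMatrix from TSV (inverse of [write_feature_tsv()])
#' @param path Path to a feature TSV.
#' @return A `FeatureMatrix`.
#' @export
read_feature_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("chrom", "start", "end", "label")
  if (!all(meta %in% names(df))) {
    stop(path, ": feature TSV must start with chrom, start, end, label")
  }
  feat <- setdiff(names(df), meta)
  X <- as.matrix(df[, feat, drop = FALSE])
  prefix <- sub(":.*$", "", feat)
  blocks <- split(feat, factor(prefix, levels = unique(prefix)))
  blk <- lapply(blocks, identity)
  fm <- list(samples = df[, c("chrom", "start", "end")],
             labels = as.integer(df$label), X = X, blocks = blk)
  class(fm) <- "FeatureMatrix"
  fm
}
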