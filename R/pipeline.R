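# End-to-end convenience: dataset -> features -> split -> forest ->
# evaluation, over either simulated or file-based inputs. This is the path
# the command-line tool and the planted-signal benchmark exercise.

#' Extract the fused feature matrix for a labelled dataset
#'
#' @param ds A `LabeledDataset`.
#' @param tracks List of `TrackSet` objects (epigenomic block); `NULL`
#'   omits the block.
#' @param pms List of `PositionMatrix` objects (motif block); `NULL` omits.
#' @param genome Named character vector (required with `pms`).
#' @param loops Loop data frame (loop block); `NULL` omits.
#' @param threshold Relative-score threshold for motif counting.
#' @return A `FeatureMatrix` with blocks named `epi`, `motif`, `loop` (as
#'   present).
#' @export
extract_features <- function(ds, tracks = NULL, pms = NULL, genome = NULL,
                             loops = NULL, threshold = 0.8) {
  samples <- dataset_samples(ds)
  regions <- samples[, c("chrom", "start", "end")]
  blocks <- list()
  if (!is.null(tracks)) {
    blocks$epi <- encode_epigenomic(regions, tracks)
  }
  if (!is.null(pms)) {
    if (is.null(genome)) stop("genome required for motif features")
    blocks$motif <- encode_motifs(regions, pms, genome, threshold)
  }
  if (!is.null(loops)) {
    blocks$loop <- encode_loops(regions, loops)
  }
  if (length(blocks) == 0) stop("no feature blocks requested")
  assemble_features(regions, samples$label, blocks)
}

#' Planted-signal benchmark: simulate, train, evaluate
#'
#' Runs the full pipeline on a synthetic study: builds the balanced
#' benchmark dataset from the simulated ORIs, extracts all three feature
#' blocks, performs the stratified split, trains the forest on the training
#' rows and evaluates on the independent rows.
#'
#' @param sim Output of [simulate_study()], or a `synth_config` (which is
#'   simulated first).
#' @param n_trees Trees per forest (default 500).
#' @param threshold Motif relative-score threshold (default 0.8).
#' @param seed Seed for dataset construction, split, and forest (defaults
#'   to the simulation's own seed).
#' @return List with `sim`, `dataset`, `fm` (FeatureMatrix), `split`,
#'   `model`, `eval` (an `EvalResult` on the independent set), and `auc`.
#' @export
run_benchmark <- function(sim, n_trees = 500, threshold = 0.8, seed = NULL) {
  if (inherits(sim, "synth_config")) sim <- simulate_study(sim)
  cfg <- sim$config
  if (is.null(seed)) seed <- cfg$seed
  ds <- build_dataset(sim$oris, gap_min = cfg$gap_min,
                      len_range = cfg$neg_len_range,
                      per_gap = cfg$negatives_per_gap,
                      ratio = 1, seed = seed)
  fm <- extract_features(ds, tracks = sim$tracks, pms = sim$pms,
                         genome = sim$genome, loops = sim$loops,
                         threshold = threshold)
  split <- stratified_split(ds, seed = seed)
  model <- train_forest(fm, split$train, n_trees = n_trees, seed = seed)
  probs <- predict_proba(model, fm, split$independent)
  ev <- evaluate_scores(probs, fm$labels[split$independent])
  list(sim = sim, dataset = ds, fm = fm, split = split, model = model,
       eval = ev, auc = ev$auc)
}
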