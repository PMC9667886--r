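---
title: "Predicting DNA replication origins from epigenomic, motif and chromatin-interaction features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DNA replication origins from epigenomic, motif and chromatin-interaction features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriforest)
```

## The problem

Eukaryotic DNA replication starts at thousands of origins (ORIs) whose
selection is regulated jointly by local chromatin state, DNA sequence, and
the three-dimensional organisation of the genome. oriforest frames origin
recognition as binary classification of genomic intervals: positive samples
are experimentally mapped ORI intervals; negative samples are fragments of
800–1000 bp drawn from the middles of inter-ORI gaps longer than 10 kb, so
they are far from any mapped origin. Three feature blocks describe each
candidate region:

* **Epigenomic block** — for each mark track (ChIP-seq peaks of histone
  modifications and transcription factors, DNase accessibility, DNA
  methylation), the *overlap ratio*: the fraction of the region's bases
  covered by the union of the mark's peaks. We chose base-coverage of the
  candidate region (rather than a peak-centric or Jaccard statistic)
  because it yields a well-defined value in $[0,1]$ per sample regardless
  of peak geometry; tracks are merged before coverage so double-covered
  bases cannot count twice.
* **Motif block** — for each position frequency matrix, the number of
  windows inside the region, on both strands, whose *relative matching
  score* reaches a threshold (default 80%). The relative score of a window
  is $(S - S_{\min})/(S_{\max} - S_{\min})$, where $S$ is the log-odds sum
  $\sum_j \log\frac{c_{b_j,j}+\epsilon}{C_j+4\epsilon} - \log \pi_{b_j}$
  with pseudocount $\epsilon$ (default 0.01) and background $\pi$ (default
  uniform), and $S_{\max}, S_{\min}$ are the best and worst attainable
  sums. This is the standard PWM-matching convention: absolute log-odds
  scores are not comparable across motifs, relative scores are. Raw counts
  (not per-kb rates) are the default feature, since positive and negative
  regions are encoded exactly alike; a per-kb switch exists because the
  two classes differ in length.
* **Chromatin-interaction block** — per loop dataset (e.g. Pol2A ChIA-PET,
  CTCF ChIA-PET, Hi-C), two features: the *interaction abundance*, i.e.
  the number of loops with at least one anchor overlapping the region
  (each loop counted once), and the *anchor overlap ratio* of the region
  against the union of the dataset's anchors. The "both anchors" reading
  of abundance is available via `both_ends = TRUE`; it is not the default
  because for sub-kilobase candidate regions both anchors of one loop
  rarely intersect a single region, which would zero the feature almost
  everywhere.

With 83 marks, 537 motifs and 3 loop datasets the fused matrix has
$83 + 537 + 3\times2 = 626$ columns, keyed `epi:<track>`, `motif:<id>`,
`loop:<dataset>:abundance|anchor_ratio` so that importance tables and
cross-cell-line feature intersections are stable under reordering.

## Classifier, importance, and feature elimination

The classifier is a random forest (ranger backend) with the package's
default parameters: 500 trees, `mtry` $=\lfloor\sqrt p\rfloor$, unlimited
depth, Gini splits, single-threaded with a fixed seed so that importances
and predictions are reproducible. Predicted probability is the fraction of
trees voting for the ORI class. Variable importance is the permutation
importance on out-of-bag samples — the mean decrease in accuracy when a
feature is shuffled — which is comparable across heterogeneous feature
blocks.

`rfe_curve()` ranks the features once by the full model's importance
(stable tie-break: score descending, then name), then retrains on nested
top-$k$ subsets over a size grid and records the evaluation AUC at each
size — the incremental-feature-selection curve. The reported optimum is
the smallest size attaining the maximal AUC. A `"recursive"` mode re-ranks
within the surviving subset before each elimination step; the default is
rank-once because a single ranking followed by subset search is the
canonical procedure and an order of magnitude cheaper. For cross-cell-line
transfer, `transfer_features()` intersects a source model's ranked
features with the marks available in the target cell lines, preserving
importance order, and the model is refit on the shared set.

Data splits follow the benchmark protocol: per class, 30% of samples are
held out as the independent set; the remainder is divided 8:2 into train
and tune sets. `subsample_imbalanced()` builds the 1:5-ratio datasets
(positive fifths against all negatives) used to check that performance is
not an artefact of class balance.

## Evaluation conventions

`roc_auc()` is the Mann–Whitney probability (ties counted half), computed
with midranks; it equals the trapezoidal area under the ROC curve.
`pr_aupr()` uses the step-wise average-precision convention
$\sum_i (R_i - R_{i-1}) P_i$ over distinct thresholds — not trapezoidal
interpolation, which is known to be optimistic for PR curves. The PR
baseline of a random ranking equals the positive-class prevalence
$n_+/(n_+ + n_-)$. `recall_at_cutoff()` counts probabilities *strictly*
above the cutoff (a probability of exactly 0.5 is not called an origin).

## Enrichment statistics

`colocalization_compare()` reduces each region to a presence/absence
indicator for the mark and applies a Welch two-sample t-test to the
indicators, which makes the test well-defined at region granularity; a
two-proportion z-test is available as an alternative. When both indicator
vectors are constant the t statistic is undefined; identical constant
proportions report $p = 1$, different ones $p = 0$. Motif enrichment uses
the $2\times2$ odds ratio $ad/bc$ with the Haldane–Anscombe $+0.5$
correction applied (and flagged) whenever a cell is zero.
`anchor_profile()` bins a ±3000 bp window around each anchor midpoint into
50 bp bins (121 bins, centred at offset 0) and averages the track's
base-coverage per bin; the window comfortably contains the few-hundred-bp
scale at which origin-proximal signals turn over. Because the absolute
scale of such meta-profiles is arbitrary, the default normalisation
divides by the mean of the outermost 10% of bins (flank normalisation);
raw coverage is available with `normalize = FALSE`. `fit_gamma()` is the
maximum-likelihood gamma fit (Newton iterations on
$\log k - \psi(k) = \log \bar x - \overline{\log x}$, scale $=\bar x/k$),
used for ORI length and inter-ORI spacing distributions; by construction
the fitted mean equals the sample mean.

## What the synthetic generator emulates

`synth_config()` defines a fully self-contained toy study so every stage
of the pipeline is testable without downloads. The defaults are the
package's reference conditions:

| parameter | default | rationale |
|---|---|---|
| genome | 2 chromosomes × 2 Mb, GC 0.41 | large enough for ~1000 origins at realistic spacing, small enough to scan in seconds |
| ORI length | gamma(shape 2, scale 150), floored at 50 bp | ~85% of origins below 500 bp, matching the observed length distribution |
| ORI spacing | gamma(shape 0.4, scale 8250), ≥ 1 bp | mean ~3.3 kb; most adjacent origins closer than 10 kb, with a heavy tail so ~10% of gaps qualify for negative sampling |
| marks | 5 informative + 45 decoys; peak present at 80% of ORIs vs 20% of background loci | a planted-signal recovery problem with a known answer |
| motifs | 3 near-deterministic PFMs of width 15, consensus planted in 30% of ORIs | planting overwrites sequence, so exhaustive-scan oracles have exact expected hits |
| loops | 1 dataset × 200 loops; anchors on a random ORI with probability 0.6, otherwise on a random locus | the anchor–origin association the interaction features are meant to pick up |
| negatives | up to 8 fragments per qualifying gap | yields a near-balanced benchmark of ~1400 samples from ~1000 origins |

A design point worth spelling out: positives (gamma lengths, mostly
100–800 bp) and negatives (800–1000 bp) differ in length *by
construction* — that is part of the benchmark definition being emulated —
so any generator whose per-region feature distributions depend on region
length would leak class information even with all enrichment parameters at
background. Early versions of the generator did exactly that (uniform
per-base peak fields hit long regions more often; fixed-width jittered
peaks cover short and long regions to different fractions; per-base-uniform
loop anchors let the forest reconstruct region length from the interaction
features; 12-mer motifs produce length-proportional chance hits at the
0.8 threshold). The released generator therefore works locus-wise: marks
and loop anchors attach to candidate loci (the ORI footprint itself, or a
1000-bp window around a candidate negative slot), a present peak covers
its locus exactly, and motifs are 15-mers whose chance-hit rate is
negligible. With every enrichment probability at its background value
(`null_synth_config()`), feature distributions are then exchangeable
between classes and the end-to-end AUC sits at chance level — which is the
property that makes the planted-signal benchmark meaningful.

What the generator does **not** emulate: read-level noise and peak-calling
artefacts, sequence composition biases (CpG islands, G-quadruplexes),
correlated mark co-occurrence, distance decay of chromatin contacts, and
the genuine length confound of real benchmarks. Passing the planted-signal
tests therefore shows that the pipeline recovers the signal it is pointed
at under controlled conditions — not that real-data accuracies transfer.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere in memory (BED native);
  conversion to 1-based closed happens only at the IRanges boundary.
  Chromosome names match as exact strings; `validate_chromosomes()`
  surfaces mismatches instead of silently dropping intervals.
* Windows containing non-ACGT characters score `NA`, are skipped by the
  scanner, and are tallied in the hit report. A region shorter than a
  motif counts 0 (not an error). A motif whose best and worst scores
  coincide (completely flat matrix) scores 1 everywhere.
* Negative sampling reads "gaps longer than 10 kb" strictly; one fragment
  per gap is centred, several are evenly spaced with at least the maximum
  fragment length between centres so fragments can never overlap each
  other or an origin. With `ratio = 1` the larger class is subsampled
  (seeded) to balance.
* Importance ties break by feature name; RFE subsets are stored in the
  original column order, which keeps refits byte-reproducible and makes
  the full-width grid point coincide with the full model.
* The gamma fit rejects samples with zero variance, non-positive values,
  or fewer than 30 observations rather than returning a degenerate
  optimum.
* Problem sizes in the test-suite are desk-scale by design: the default
  synthetic study (2 × 2 Mb, ~1000 origins, ~1400-sample benchmark, 500
  trees) runs end-to-end in well under a minute, and the dimension
  accounting check scans 537 synthetic PFMs over a 20-region subset.

## Worked example

```{r example, eval = FALSE}
library(oriforest)

sim <- simulate_study(synth_config(seed = 1))
bench <- run_benchmark(sim)
bench$eval
#> EvalResult: 221 pos / 221 neg | AUC 0.9917 | AUPR 0.9917 (baseline 0.5000)

head(importance_ranking(bench$model), 3)
#>      feature importance rank
#> 1 epi:inf_05 0.05523443    1
#> 2 epi:inf_04 0.04474210    2
#> 3 epi:inf_02 0.04465818    3

fm_epi <- subset_features(bench$fm, bench$fm$blocks$epi)
rfe_curve(fm_epi, bench$split$train, bench$split$independent,
          size_grid = c(50, 20, 10, 5, 2, 1), seed = 1)
#> RfeTrace (rank_once): 6 sizes, best_size 50 (AUC 0.9786)
#>  size       auc
#>    50 0.9785733
#>    20 0.9749493
#>    10 0.9746934
#>     5 0.9783276
#>     2 0.8797424
#>     1 0.7692308
```

## Known limitations

* The forest is the only learner; no probability calibration or
  hyperparameter search is provided, by design.
* Loop inputs must be pre-exported to BEDPE; binary Hi-C containers are
  out of scope, and loop resolution is left to the input file.
* The "both ends" abundance semantics is interpreted per sample region;
  the six-feature dimension count constrains the number of loop features,
  not this choice.
* Gene-ontology enrichment of origin-overlapping genes requires external
  annotation databases and is deliberately absent.
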