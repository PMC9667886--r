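# oriforest

Random-forest identification of DNA replication origins (ORIs) from three
kinds of functional-genomics evidence, for researchers studying where
eukaryotic replication initiates and which chromatin features mark those
sites.

Replication origins are genomic intervals, typically a few hundred base
pairs, whose selection is shaped by chromatin state, DNA sequence, and 3D
genome organisation. oriforest encodes each candidate region with three
feature blocks and classifies it ORI vs non-ORI:

- **epigenomic marks** — per mark, the overlap ratio: the fraction of the
  region's bases covered by the union of the mark's peaks (BED/narrowPeak
  input), a value in [0, 1];
- **DNA motifs** — per position weight matrix (JASPAR PFM text input), the
  number of windows on either strand whose relative matching score
  (S − S<sub>min</sub>)/(S<sub>max</sub> − S<sub>min</sub>) reaches 0.8;
- **chromatin loops** — per interaction dataset (BEDPE input, e.g.
  ChIA-PET or Hi-C loops), the interaction abundance (loops with an anchor
  overlapping the region) and the anchor overlap ratio.

The blocks are fused into one labelled feature matrix (83 marks + 537
motifs + 3 loop datasets → 626 columns) and fed to a random forest
(ranger backend, default parameters, deterministic under a fixed seed).
Out-of-bag permutation importance (mean decrease in accuracy) ranks the
features, and recursive feature elimination retrains on nested top-k
subsets to find the smallest subset that predicts as well as the full set.
Negative samples are built from the genome itself: 800–1000 bp fragments
centred in inter-ORI gaps longer than 10 kb. The package also ships the
descriptive statistics used around such models (colocalization tests,
motif odds ratios, anchor-centred meta-profiles, gamma fits to ORI length
and spacing) and a fully synthetic data generator, so every stage runs and
is tested without any external download.

## Worked example

A self-contained study: simulate a toy genome with planted signal, build
the benchmark dataset, extract all three feature blocks, train, evaluate
on the held-out independent set, and run feature elimination.

```r
library(oriforest)

sim   <- simulate_study(synth_config(seed = 1))
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

Reading the output: the independent-set AUC of 0.9917 shows the forest
recovers the planted signal (five informative marks present at 80% of
origins vs 20% of background loci, planted motifs, ORI-biased loop
anchors); the importance ranking puts exactly those informative marks
(`epi:inf_*`) on top; and the elimination curve shows five features carry
essentially all of the epigenomic block's information (AUC 0.9783 at k = 5
vs 0.9786 at k = 50), collapsing only below that.

A command-line interface over the same functions is installed with the
package (`system.file("cli", "oriforest.R", package = "oriforest")`), with
subcommands `simulate`, `build-dataset`, `extract-features`, `train`,
`rfe`, `evaluate`, `predict`, `enrich`, `transfer`.

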