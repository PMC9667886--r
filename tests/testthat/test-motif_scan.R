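test_that("relative score is 1 at the consensus and 0 at the anti-consensus", {
  withr::local_seed(3)
  for (i in 1:10) {
    pm <- oracle_random_pm(sprintf("m%d", i), sample(4:10, 1))
    lo <- pm$log_odds
    best <- paste(c("A", "C", "G", "T")[apply(lo, 2, which.max)], collapse = "")
    worst <- paste(c("A", "C", "G", "T")[apply(lo, 2, which.min)], collapse = "")
    expect_equal(relative_score(pm, best), 1)
    expect_equal(relative_score(pm, worst), 0)
  }
})

test_that("relative score matches the hand-summed log-odds normalisation", {
  pm <- position_matrix("m1", matrix(c(4, 0, 0, 0, 0, 4, 0, 0), 4, 2),
                        pseudocount = 0.01)
  # independent arithmetic: per-cell log((count + pc)/(colsum + 4 pc)/0.25)
  lo <- function(count) log(((count + 0.01) / (4 + 0.04)) / 0.25)
  s_aa <- lo(4) + lo(0)
  s_max <- lo(4) + lo(4)
  s_min <- lo(0) + lo(0)
  expect_equal(relative_score(pm, "AA"), (s_aa - s_min) / (s_max - s_min))
  expect_equal(relative_score(pm, "AC"), 1)
  expect_equal(relative_score(pm, "TT"), 0)
  expect_true(is.na(relative_score(pm, "AN")))
  expect_error(relative_score(pm, "ACG"), "window length")
})

test_that("count_occurrences handles short regions and exact consensus", {
  pm <- position_matrix("m", matrix(c(9, 0, 0, 0, 0, 9, 0, 0, 0, 0, 9, 0),
                                    4, 3))  # consensus ACG, not palindromic
  genome <- c(chr1 = "TTACGTT")
  expect_equal(count_occurrences(pm, list(chrom = "chr1", start = 0, end = 2),
                                 genome), 0)  # region shorter than motif
  expect_equal(count_occurrences(pm, list(chrom = "chr1", start = 2, end = 5),
                                 genome, threshold = 1), 1)
})

test_that("both-strand counts match the exhaustive window oracle", {
  withr::local_seed(9)
  pm <- position_matrix("planted", {
    m <- matrix(0, 4, 6)
    m[cbind(encode_dna("ACGGTA"), 1:6)] <- 12
    m
  })
  # 30 bp with one forward and one reverse-complement consensus instance
  seq <- paste0(random_dna(5), "ACGGTA", random_dna(8), "TACCGT",
                random_dna(5))
  genome <- c(chr1 = seq)
  region <- list(chrom = "chr1", start = 0, end = nchar(seq))
  n <- count_occurrences(pm, region, genome, threshold = 0.95)
  expect_gte(n, 2)
  expect_equal(n, oracle_count_occurrences(pm, seq, 0.95))
  # random matrices over random sequences, random thresholds
  for (i in 1:12) {
    pm_i <- oracle_random_pm(sprintf("r%d", i), sample(3:7, 1))
    s <- random_dna(sample(20:60, 1))
    thr <- runif(1, 0.5, 1)
    expect_equal(
      count_occurrences(pm_i, list(chrom = "c", start = 0, end = nchar(s)),
                        c(c = s), thr),
      oracle_count_occurrences(pm_i, s, thr))
  }
})

test_that("the two-strand scan is strand-symmetric", {
  withr::local_seed(21)
  for (i in 1:10) {
    pm <- oracle_random_pm(sprintf("s%d", i), sample(4:8, 1))
    s <- random_dna(50)
    rc <- oracle_revcomp(s)
    thr <- runif(1, 0.6, 0.95)
    n1 <- count_occurrences(pm, list(chrom = "c", start = 0, end = 50),
                            c(c = s), thr)
    n2 <- count_occurrences(pm, list(chrom = "c", start = 0, end = 50),
                            c(c = rc), thr)
    expect_equal(n1, n2)
  }
})

test_that("counts are monotone in threshold and saturate as threshold -> 0", {
  withr::local_seed(5)
  pm <- oracle_random_pm("m", 5)
  s <- random_dna(40)
  genome <- c(c = s)
  region <- list(chrom = "c", start = 0, end = 40)
  counts <- vapply(c(0.2, 0.5, 0.8, 0.95),
                   function(t) count_occurrences(pm, region, genome, t),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  # as threshold -> 0+ every window counts except ones sitting exactly at
  # the minimum attainable score (relative score 0)
  all_scores <- unlist(lapply(c(s, oracle_revcomp(s)), function(str)
    vapply(seq_len(40 - 5 + 1), function(i)
      relative_score(pm, substr(str, i, i + 4)), numeric(1))))
  n_at_min <- sum(abs(all_scores) < 1e-9)
  expect_equal(count_occurrences(pm, region, genome, threshold = 1e-9),
               2 * (40 - 5 + 1) - n_at_min)
  expect_gte(2 * (40 - 5 + 1) - n_at_min, 0.9 * 2 * (40 - 5 + 1))
})

test_that("windows containing ambiguity codes are skipped and tallied", {
  pm <- position_matrix("m", matrix(c(4, 0, 0, 0, 0, 4, 0, 0), 4, 2))
  genome <- c(c = "ACNAC")
  hits <- motif_hits(pm, list(chrom = "c", start = 0, end = 5), genome,
                     threshold = 0.9)
  expect_equal(nrow(hits), 2)  # "AC" at 0 and 3; windows touching N skipped
  expect_equal(hits$start, c(0, 3))
  expect_true(attr(hits, "n_skipped_windows") > 0)
})

test_that("motif_hits reports genomic coordinates and strands correctly", {
  pm <- position_matrix("m", {
    m <- matrix(0, 4, 4)
    m[cbind(encode_dna("ACGG"), 1:4)] <- 8
    m
  })
  #           0123456789012345
  seq <- "TTTTACGGTTCCGTTT"  # fwd instance at 4, rc instance (CCGT) at 10
  genome <- c(chr5 = seq)
  hits <- motif_hits(pm, list(chrom = "chr5", start = 0, end = 16), genome,
                     threshold = 1)
  expect_equal(nrow(hits), 2)
  fwd <- hits[hits$strand == "+", ]
  rev <- hits[hits$strand == "-", ]
  expect_equal(c(fwd$start, fwd$end), c(4, 8))
  expect_equal(c(rev$start, rev$end), c(10, 14))
  expect_equal(genome_subseq(genome, "chr5", rev$start, rev$end), "CCGT")
})
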