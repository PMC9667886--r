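test_that("epigenomic block has one [0,1] column per track, in input order", {
  samples <- data.frame(chrom = "chr1", start = c(100, 400), end = c(200, 600))
  tracks <- list(
    new_track("h3k4me1", data.frame(chrom = "chr1", start = 50, end = 300)),
    new_track("dnase", data.frame(chrom = "chr1", start = 450, end = 500)),
    new_track("ctcf", data.frame(chrom = "chr2", start = 0, end = 10))
  )
  X <- encode_epigenomic(samples, tracks)
  expect_equal(dim(X), c(2, 3))
  expect_equal(colnames(X), c("epi:h3k4me1", "epi:dnase", "epi:ctcf"))
  expect_true(all(X >= 0 & X <= 1))
  expect_equal(unname(X[1, "epi:h3k4me1"]), 1)  # sample fully inside the peak
  expect_equal(unname(X[2, "epi:dnase"]), 0.25)
  expect_equal(unname(X[, "epi:ctcf"]), c(0, 0))
  dup <- list(tracks[[1]], tracks[[1]])
  expect_error(encode_epigenomic(samples, dup), "duplicate track names")
})

test_that("epigenomic block equals the per-cell base-enumeration oracle", {
  withr::local_seed(14)
  samples <- data.frame(chrom = "chr1", start = c(0, 90, 210, 350, 480),
                        end = c(80, 200, 330, 460, 600))
  tracks <- lapply(1:3, function(k) {
    start <- sample(0:550, 6)
    new_track(paste0("t", k),
              data.frame(chrom = "chr1", start = start,
                         end = start + sample(10:120, 6, replace = TRUE)))
  })
  X <- encode_epigenomic(samples, tracks)
  for (i in 1:5) for (k in 1:3) {
    expect_equal(unname(X[i, k]),
                 oracle_overlap_ratio(samples[i, ], tracks[[k]]$intervals))
  }
})

test_that("motif block counts match the exhaustive-scan oracle", {
  withr::local_seed(30)
  genome <- c(chr1 = random_dna(600))
  samples <- data.frame(chrom = "chr1", start = c(0, 150, 380),
                        end = c(120, 320, 560))
  pms <- lapply(1:3, function(k) oracle_random_pm(sprintf("MA%04d.1", k), 5))
  X <- encode_motifs(samples, pms, genome, threshold = 0.85)
  expect_equal(colnames(X), paste0("motif:", sapply(pms, `[[`, "motif_id")))
  expect_true(all(X == round(X) & X >= 0))
  for (i in 1:3) for (k in 1:3) {
    seq <- genome_subseq(genome, "chr1", samples$start[i], samples$end[i])
    expect_equal(unname(X[i, k]), oracle_count_occurrences(pms[[k]], seq, 0.85))
  }
  expect_error(encode_motifs(samples, c(pms, pms[1]), genome),
               "motif_id collision")
})

test_that("loop block counts each loop once and covers anchors correctly", {
  sample1 <- data.frame(chrom = "chr1", start = 1000, end = 1500)
  loops <- data.frame(
    dataset = "pol2a",
    chrom1 = c("chr1", "chr1", "chr1", "chr2"),
    start1 = c(900, 1100, 5000, 0),
    end1   = c(1600, 1200, 5100, 50),
    chrom2 = c("chr5", "chr1", "chr1", "chr2"),
    start2 = c(0, 1400, 8000, 100),
    end2   = c(100, 1450, 8100, 150)
  )
  X <- encode_loops(sample1, loops)
  # loop 1: anchor1 covers the sample entirely; loop 2: both anchors
  # overlap but the loop counts once; loops 3-4 are elsewhere
  expect_equal(unname(X[1, "loop:pol2a:abundance"]), 2)
  expect_equal(unname(X[1, "loop:pol2a:anchor_ratio"]), 1)
  # enumeration oracle for the abundance
  n_overlap <- sum(apply(loops, 1, function(lp) {
    o1 <- lp["chrom1"] == "chr1" &&
      as.integer(lp["start1"]) < 1500 && as.integer(lp["end1"]) > 1000
    o2 <- lp["chrom2"] == "chr1" &&
      as.integer(lp["start2"]) < 1500 && as.integer(lp["end2"]) > 1000
    o1 || o2
  }))
  expect_equal(unname(X[1, "loop:pol2a:abundance"]), n_overlap)
  # strict both-ends reading only keeps loop 2
  Xb <- encode_loops(sample1, loops, both_ends = TRUE)
  expect_equal(unname(Xb[1, "loop:pol2a:abundance"]), 1)
  # a sample far from all loops
  far <- data.frame(chrom = "chr9", start = 0, end = 500)
  Xf <- encode_loops(far, loops)
  expect_equal(unname(Xf[1, ]), c(0, 0))
  bad <- loops
  bad$dataset[1] <- ""
  expect_error(encode_loops(sample1, bad), "dataset")
})

test_that("assembled width is the sum of block widths with 2 columns per
           loop dataset", {
  samples <- data.frame(chrom = "chr1", start = c(0, 100), end = c(50, 150))
  labels <- c(1, 0)
  mk <- function(p, prefix) {
    m <- matrix(runif(2 * p), 2, p)
    colnames(m) <- paste0(prefix, seq_len(p))
    m
  }
  fm <- assemble_features(samples, labels,
                          list(epi = mk(4, "epi:t"), motif = mk(7, "motif:m"),
                               loop = mk(2, "loop:l")))
  expect_equal(ncol(fm$X), 13)
  expect_equal(lengths(fm$blocks), c(epi = 4L, motif = 7L, loop = 2L))
  single <- assemble_features(samples, labels, list(epi = mk(3, "epi:t")))
  expect_equal(ncol(single$X), 3)
  expect_error(
    assemble_features(samples, labels, list(epi = mk(3, "epi:t")[1, , drop = FALSE])),
    "row-count mismatch")
})

test_that("feature values do not depend on sample ordering", {
  withr::local_seed(8)
  genome <- c(chr1 = random_dna(2000))
  samples <- data.frame(chrom = "chr1", start = c(0, 300, 700, 1200),
                        end = c(200, 500, 1000, 1500))
  tracks <- list(new_track("t1", data.frame(chrom = "chr1",
                                            start = c(100, 800),
                                            end = c(400, 1300))))
  pms <- list(oracle_random_pm("m1", 5))
  loops <- data.frame(dataset = "hic", chrom1 = "chr1", start1 = 250,
                      end1 = 350, chrom2 = "chr1", start2 = 900, end2 = 950)
  enc <- function(s) cbind(encode_epigenomic(s, tracks),
                           encode_motifs(s, pms, genome),
                           encode_loops(s, loops))
  X <- enc(samples)
  perm <- c(3, 1, 4, 2)
  Xp <- enc(samples[perm, ])
  expect_equal(Xp, X[perm, ], ignore_attr = TRUE)
})

test_that("block retention reports the percentage of each block kept", {
  blocks <- list(epi = paste0("epi:t", 1:83), motif = paste0("motif:m", 1:537),
                 loop = paste0("loop:l", 1:6))
  selected <- c(paste0("epi:t", 1:29), paste0("motif:m", 1:29),
                paste0("loop:l", 1:2))
  ret <- block_retention(selected, blocks)
  expect_equal(round(ret$percentage[ret$block == "epi"], 1), 34.9)
  expect_equal(round(ret$percentage[ret$block == "motif"], 1), 5.4)
  expect_equal(ret$selected, c(29L, 29L, 2L))
})

test_that("feature TSV round-trips samples, labels, matrix and blocks", {
  pl <- planted_matrix(n = 20, n_inf = 2, n_dec = 3, seed = 4)
  fm <- make_fm(pl$X, pl$labels)
  f <- withr::local_tempfile()
  write_feature_tsv(fm, f)
  back <- read_feature_tsv(f)
  expect_equal(back$X, fm$X, ignore_attr = TRUE)
  expect_equal(back$labels, fm$labels)
  expect_equal(unname(lengths(back$blocks)), unname(lengths(fm$blocks)))
})
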