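# Fully self-contained synthetic inputs with the statistical structure the
# classifier assumes: a toy genome with gamma-distributed ORI lengths and
# inter-ORI spacings, mark peaks enriched at ORIs, planted motif instances,
# and chromatin loops with ORI-biased anchors.
#
# Mark placement is locus-based rather than a per-base-uniform peak field:
# each candidate locus (an ORI, or a candidate negative slot in a long
# inter-ORI gap) receives a peak with a class-dependent probability
# (p_at_ori at ORIs for informative marks, p_background everywhere else and
# for decoys). This realises "a rate implying p_background per non-ORI
# region" exactly and — because positive (gamma-length) and negative
# (800-1000 bp) regions differ in length by construction — keeps the
# no-signal configuration genuinely signal-free: a uniform peak field would
# hit longer regions more often and leak region length into every feature.

#' Synthetic-study configuration
#'
#' Defaults define the reference study conditions: 2 chromosomes x 2 Mb,
#' ~1000 ORIs with gamma(2, 150) lengths (~85% shorter than 500 bp) and
#' gamma(0.4, 8250) spacings (mean ~3.3 kb; most adjacent ORIs closer than
#' 10 kb, with a heavy enough tail that ~10% of gaps qualify for negative
#' sampling), 5 informative + 45 decoy marks with 1000-bp peaks present at
#' 80% of ORIs vs 20% of background loci, 3 motifs of width 12 planted in
#' 30% of ORIs, and one loop dataset of 200 loops whose anchors hit ORIs
#' 60% of the time.
#'
#' @param n_chromosomes,chrom_length Genome dimensions (bp).
#' @param n_oris Total ORIs to place (split evenly across chromosomes).
#' @param ori_shape,ori_scale Gamma parameters of ORI length (bp).
#' @param spacing_shape,spacing_scale Gamma parameters of inter-ORI
#'   spacing (bp).
#' @param n_informative_marks,n_decoy_marks Mark counts.
#' @param p_at_ori,p_background Peak presence probabilities at ORIs
#'   (informative marks) and at background loci (all marks).
#' @param peak_length Peak width in bp.
#' @param n_motifs,motif_length Motif count and width; columns are
#'   near-deterministic so chance hits at the 0.8 relative-score threshold
#'   are rare.
#' @param motif_planting_rate Probability a given motif's consensus is
#'   planted inside a given ORI.
#' @param n_loop_datasets,n_loops,anchor_length,anchor_at_ori Loop-set
#'   geometry and the probability an anchor is centred on an ORI (0 means
#'   anchors are uniform).
#' @param gc_content Genome GC fraction.
#' @param gap_min,neg_len_range,negatives_per_gap Negative-sampling
#'   parameters (shared with [build_negatives()]).
#' @param seed Mandatory integer seed; every output is deterministic in
#'   (config, seed).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_chromosomes = 2, chrom_length = 2e6,
                         n_oris = 1000,
                         ori_shape = 2, ori_scale = 150,
                         spacing_shape = 0.4, spacing_scale = 8250,
                         n_informative_marks = 5, n_decoy_marks = 45,
                         p_at_ori = 0.8, p_background = 0.2,
                         peak_length = 1000,
                         n_motifs = 3, motif_length = 15,
                         motif_planting_rate = 0.3,
                         n_loop_datasets = 1, n_loops = 200,
                         anchor_length = 1000, anchor_at_ori = 0.6,
                         gc_content = 0.41,
                         gap_min = 10000, neg_len_range = c(800, 1000),
                         negatives_per_gap = 8,
                         seed = 1) {
  cfg <- as.list(environment())
  probs <- c(cfg$p_at_ori, cfg$p_background, cfg$motif_planting_rate,
             cfg$anchor_at_ori, cfg$gc_content)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(c(cfg$chrom_length, cfg$peak_length, cfg$anchor_length,
            cfg$ori_scale, cfg$spacing_scale) <= 0)) {
    stop("lengths and scales must be positive")
  }
  if (is.null(seed) || is.na(seed)) stop("seed is mandatory")
  per_chrom <- cfg$n_oris / cfg$n_chromosomes
  footprint <- per_chrom * (cfg$ori_shape * cfg$ori_scale +
                              cfg$spacing_shape * cfg$spacing_scale)
  if (cfg$n_oris > 0 && footprint > cfg$chrom_length) {
    stop(sprintf(
      "expected ORI footprint (%.0f bp/chromosome) exceeds chromosome length (%d bp)",
      footprint, as.integer(cfg$chrom_length)))
  }
  class(cfg) <- "synth_config"
  cfg
}

#' No-signal variant of a configuration
#'
#' Sets every enrichment parameter to its background value (marks
#' uninformative, no motif planting, uniform loop anchors) while keeping
#' the geometry, for null-calibration runs.
#'
#' @param config A `synth_config` (default: the package defaults).
#' @param seed Optional seed override.
#' @return A `synth_config`.
#' @export
null_synth_config <- function(config = synth_config(), seed = NULL) {
  config$p_at_ori <- config$p_background
  config$motif_planting_rate <- 0
  config$anchor_at_ori <- 0
  if (!is.null(seed)) config$seed <- seed
  config
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "synth_config: %d x %.1f Mb, %d ORIs, %d+%d marks (p %.2f/%.2f), %d motifs, %d loop set(s), seed %d\n",
    x$n_chromosomes, x$chrom_length / 1e6, x$n_oris,
    x$n_informative_marks, x$n_decoy_marks, x$p_at_ori, x$p_background,
    x$n_motifs, x$n_loop_datasets, x$seed))
  invisible(x)
}

#' @noRd
.random_seq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate the toy genome and its ORI intervals
#'
#' Random sequence at the configured GC content; ORIs are laid down
#' left-to-right with gamma spacings and gamma lengths (floored at 50 bp),
#' clipped when a chromosome is full. Deterministic per (config, seed).
#'
#' @param config A `synth_config`.
#' @return List with `genome` (named character vector) and `oris`
#'   (interval data frame).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$seed, {
    chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
    genome <- setNames(
      vapply(chroms, function(ch)
        .random_seq(config$chrom_length, config$gc_content), character(1)),
      chroms)
    per_chrom <- ceiling(config$n_oris / config$n_chromosomes)
    oris <- list()
    if (config$n_oris > 0) {
      for (ch in chroms) {
        pos <- 0
        rows <- vector("list", per_chrom)
        n_placed <- 0
        for (i in seq_len(per_chrom)) {
          gap <- max(1, round(rgamma(1, shape = config$spacing_shape,
                                     scale = config$spacing_scale)))
          len <- max(50, round(rgamma(1, shape = config$ori_shape,
                                      scale = config$ori_scale)))
          start <- pos + gap
          if (start + len > config$chrom_length) break
          rows[[i]] <- data.frame(chrom = ch, start = start,
                                  end = start + len)
          pos <- start + len
          n_placed <- n_placed + 1
        }
        oris[[ch]] <- do.call(rbind, rows[seq_len(n_placed)])
      }
    }
    oris <- do.call(rbind, oris)
    if (is.null(oris)) oris <- .empty_intervals()
    rownames(oris) <- NULL
    list(genome = genome, oris = oris)
  })
}

#' Generate mark tracks with ORI-enriched peaks
#'
#' Informative marks (`inf_*`) carry a peak at each ORI with probability
#' `p_at_ori` and at each candidate background locus with probability
#' `p_background`; decoy marks (`dec_*`) use `p_background` everywhere.
#' Background loci are the [negative_slots()] of the configured
#' negative-sampling geometry. A present peak coincides with the locus
#' footprint — the ORI interval itself, or a `peak_length` window around a
#' background slot centre — so peaks never spill onto neighbouring loci and
#' a region's overlap ratio is exactly 1 when its locus carries the mark
#' and 0 otherwise; presence probability is then the only class
#' difference, which keeps the no-signal configuration exactly null.
#'
#' @param config A `synth_config`.
#' @param oris Interval data frame of ORIs (from [generate_genome()]).
#' @return List of `TrackSet` objects (informative marks first).
#' @export
generate_marks <- function(config, oris) {
  stopifnot(inherits(config, "synth_config"))
  if (nrow(oris) == 0) stop("ORIs required to place marks")
  slots <- negative_slots(oris, config$gap_min, config$neg_len_range,
                          config$negatives_per_gap)
  half <- floor(config$peak_length / 2)
  loci <- rbind(
    data.frame(chrom = oris$chrom, start = oris$start, end = oris$end,
               at_ori = TRUE),
    data.frame(chrom = slots$chrom,
               start = pmax(0L, as.integer(slots$center - half)),
               end = as.integer(slots$center - half + config$peak_length),
               at_ori = FALSE)
  )
  mark_names <- c(sprintf("inf_%02d", seq_len(config$n_informative_marks)),
                  sprintf("dec_%02d", seq_len(config$n_decoy_marks)))
  informative <- c(rep(TRUE, config$n_informative_marks),
                   rep(FALSE, config$n_decoy_marks))
  .with_seed(config$seed + 1L, {
    tracks <- vector("list", length(mark_names))
    for (m in seq_along(mark_names)) {
      p <- ifelse(loci$at_ori & informative[m],
                  config$p_at_ori, config$p_background)
      present <- runif(nrow(loci)) < p
      tracks[[m]] <- new_track(
        mark_names[m],
        loci[present, c("chrom", "start", "end"), drop = FALSE],
        "synthetic")
    }
    tracks
  })
}

#' Generate motifs (planted in ORIs) and chromatin loops
#'
#' Creates `n_motifs` near-deterministic PFMs with random consensus
#' sequences, plants each motif's consensus (random strand) inside each ORI
#' with probability `motif_planting_rate` by overwriting the genome
#' sequence — so exhaustive-scan oracles have exact expected hits — and
#' writes loop datasets whose anchors are centred on a random ORI with
#' probability `anchor_at_ori` and placed uniformly otherwise.
#'
#' @param config A `synth_config`.
#' @param oris Interval data frame of ORIs.
#' @param genome Named character vector (from [generate_genome()]).
#' @return List with `pms` (PositionMatrix list), `genome` (modified
#'   sequences), `loops` (loop data frame).
#' @export
generate_motifs_and_loops <- function(config, oris, genome) {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$seed + 2L, {
    L <- config$motif_length
    pms <- list()
    cons <- character(config$n_motifs)
    for (k in seq_len(config$n_motifs)) {
      cons[k] <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                       collapse = "")
      counts <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
      counts[cbind(encode_dna(cons[k]), seq_len(L))] <- 20
      id <- sprintf("SYN%03d", k)
      pms[[id]] <- position_matrix(id, counts)
    }
    if (nrow(oris) > 0 && config$motif_planting_rate > 0) {
      for (k in seq_len(config$n_motifs)) {
        plant <- runif(nrow(oris)) < config$motif_planting_rate
        for (i in which(plant)) {
          olen <- oris$end[i] - oris$start[i]
          if (olen < L) {
            warning("motif longer than ORI; skipped")
            next
          }
          offset <- sample.int(olen - L + 1L, 1L) - 1L
          instance <- cons[k]
          if (runif(1) < 0.5) {
            instance <- as.character(
              Biostrings::reverseComplement(Biostrings::DNAString(instance)))
          }
          at <- oris$start[i] + offset
          substr(genome[[oris$chrom[i]]], at + 1L, at + L) <- instance
        }
      }
    }
    loops <- list()
    slots <- negative_slots(oris, config$gap_min, config$neg_len_range,
                            config$negatives_per_gap)
    half <- floor(config$anchor_length / 2)
    for (d in seq_len(config$n_loop_datasets)) {
      ds <- sprintf("loop%d", d)
      # anchors land on candidate loci (same footprints as the mark peaks):
      # a random ORI with probability anchor_at_ori, otherwise uniformly on
      # any locus (ORI or background slot) — so the loop block, like the
      # mark block, carries class signal only through the ORI bias of its
      # anchors, and anchor_at_ori = 0 is exactly exchangeable across
      # classes
      st <- pmax(0L, as.integer(slots$center - half))
      loci_fp <- rbind(oris[, c("chrom", "start", "end")],
                       data.frame(chrom = slots$chrom, start = st,
                                  end = st + config$anchor_length))
      anchor <- function() {
        n <- config$n_loops
        use_ori <- nrow(oris) > 0 & runif(n) < config$anchor_at_ori
        out <- data.frame(chrom = character(n), start = integer(n),
                          end = integer(n))
        if (any(use_ori)) {
          pick <- sample.int(nrow(oris), sum(use_ori), replace = TRUE)
          out[use_ori, ] <- oris[pick, c("chrom", "start", "end")]
        }
        if (any(!use_ori)) {
          pick <- sample.int(nrow(loci_fp), sum(!use_ori), replace = TRUE)
          out[!use_ori, ] <- loci_fp[pick, ]
        }
        out
      }
      a1 <- anchor()
      a2 <- anchor()
      loops[[d]] <- data.frame(dataset = ds,
                               chrom1 = a1$chrom, start1 = a1$start,
                               end1 = a1$end,
                               chrom2 = a2$chrom, start2 = a2$start,
                               end2 = a2$end, stringsAsFactors = FALSE)
    }
    loops <- if (length(loops)) do.call(rbind, loops) else NULL
    list(pms = pms, genome = genome, loops = loops)
  })
}

#' Run the whole generator, optionally writing pipeline-format files
#'
#' @param config A `synth_config`.
#' @param dir Optional output directory; when given, writes `genome.fa`,
#'   `oris.bed`, one BED per mark under `marks/`, `motifs.pfm`, one BEDPE
#'   per loop dataset, and `config.yaml`.
#' @return List with `config`, `genome`, `oris`, `tracks`, `pms`, `loops`.
#' @export
simulate_study <- function(config = synth_config(), dir = NULL) {
  gen <- generate_genome(config)
  tracks <- generate_marks(config, gen$oris)
  ml <- generate_motifs_and_loops(config, gen$oris, gen$genome)
  sim <- list(config = config, genome = ml$genome, oris = gen$oris,
              tracks = tracks, pms = ml$pms, loops = ml$loops)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "marks"), showWarnings = FALSE)
    write_fasta(sim$genome, file.path(dir, "genome.fa"))
    write_bed(sim$oris, file.path(dir, "oris.bed"))
    for (tr in tracks) {
      write_bed(tr, file.path(dir, "marks", paste0(tr$name, ".bed")))
    }
    write_jaspar_pfm(sim$pms, file.path(dir, "motifs.pfm"))
    for (ds in unique(sim$loops$dataset)) {
      write_bedpe(sim$loops[sim$loops$dataset == ds, ],
                  file.path(dir, paste0(ds, ".bedpe")))
    }
    cfg <- unclass(config)
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  }
  sim
}
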