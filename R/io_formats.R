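# Readers and writers for the external formats the pipeline touches:
# BED/narrowPeak, BEDPE, JASPAR PFM text, FASTA, and the feature-matrix TSV.
# All in-memory coordinates are 0-based half-open, exactly as stored in BED.

#' Construct a TrackSet
#'
#' A TrackSet is one named collection of genomic intervals, typically the
#' peak calls of a single epigenomic mark. Intervals are kept sorted by
#' (chromosome, start); coordinates are 0-based half-open.
#'
#' @param name Short identifier, e.g. the mark name.
#' @param intervals Data frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param source_path Provenance string (file of origin), or `NA`.
#' @return An object of class `TrackSet`.
#' @export
new_track <- function(name, intervals, source_path = NA_character_) {
  .check_intervals(intervals, what = sprintf("track '%s'", name))
  obj <- list(name = name,
              intervals = .sort_intervals(intervals),
              source_path = source_path)
  class(obj) <- "TrackSet"
  obj
}

#' @export
print.TrackSet <- function(x, ...) {
  cat(sprintf("TrackSet '%s': %d intervals on %d chromosome(s)\n",
              x$name, nrow(x$intervals), length(unique(x$intervals$chrom))))
  invisible(x)
}

.is_track <- function(x) inherits(x, "TrackSet")

#' Read a BED or narrowPeak file into a TrackSet
#'
#' Track definition lines (`track`, `browser`) and `#` comments are skipped.
#' narrowPeak/broadPeak files are accepted because only the first columns
#' (and optionally name/score/strand) are used; signal columns are ignored.
#' Coordinates are kept 0-based half-open exactly as stored. Chromosome
#' names are taken verbatim (no "chr" aliasing).
#'
#' @param path Path to a BED-like file.
#' @param min_columns Minimum number of tab-separated fields each data line
#'   must have (at least 3).
#' @param name Track name; defaults to the file name without extension.
#' @return A [new_track()] `TrackSet`, sorted by (chrom, start). An empty
#'   file (or one containing only comments) yields an empty TrackSet.
#' @export
read_bed <- function(path, min_columns = 3L, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  min_columns <- max(3L, as.integer(min_columns))
  if (is.null(name)) {
    name <- sub("\\.(bed|narrowPeak|broadPeak|txt|tsv)$", "", basename(path))
  }
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(#|browser([[:space:]]|$)|track([[:space:]]|$))", lines)
  idx <- which(keep)
  if (length(idx) == 0) return(new_track(name, .empty_intervals(), path))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < min_columns)
  if (length(bad)) {
    stop(sprintf("%s line %d: expected >= %d tab-separated fields, found %d",
                 path, idx[bad[1]], min_columns, nf[bad[1]]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("%s line %d: non-integer coordinates", path, idx[bad[1]]))
  }
  bad <- which(start > end)
  if (length(bad)) {
    stop(sprintf("%s line %d: start > end", path, idx[bad[1]]))
  }
  bad <- which(start < 0)
  if (length(bad)) {
    stop(sprintf("%s line %d: negative coordinate", path, idx[bad[1]]))
  }
  iv <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (all(nf >= 4L)) iv$name <- vapply(fields, `[[`, character(1), 4L)
  if (all(nf >= 5L)) iv$score <- vapply(fields, `[[`, character(1), 5L)
  if (all(nf >= 6L)) iv$strand <- vapply(fields, `[[`, character(1), 6L)
  new_track(name, iv, path)
}

#' Write a TrackSet (or interval data frame) as BED
#'
#' Writes exactly the columns present (chrom, start, end, then name, score,
#' strand if available), so `write_bed(read_bed(f))` reproduces coordinates
#' and names bit-exactly for well-formed input.
#'
#' @param x A `TrackSet` or an interval data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- if (.is_track(x)) x$intervals else x
  .check_intervals(df, "write_bed input")
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  write.table(df[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE file of chromatin loops
#'
#' Each record contributes one loop with two anchor intervals, tagged with
#' `dataset_name`. Anchors are kept in file order (no canonical swapping)
#' and interchromosomal loops are preserved.
#'
#' @param path Path to a BEDPE file (>= 6 tab-separated fields per line).
#' @param dataset_name Tag identifying the interaction dataset, e.g.
#'   `"pol2a_chiapet"`, `"ctcf_chiapet"`, `"hic"`.
#' @return A data frame with columns `dataset`, `chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2` (0-based half-open anchors); zero rows for
#'   an empty file.
#' @export
read_bedpe <- function(path, dataset_name) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!nzchar(dataset_name)) stop("dataset_name must be non-empty")
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(#|browser([[:space:]]|$)|track([[:space:]]|$))", lines)
  idx <- which(keep)
  empty <- data.frame(dataset = character(),
                      chrom1 = character(), start1 = integer(), end1 = integer(),
                      chrom2 = character(), start2 = integer(), end2 = integer(),
                      stringsAsFactors = FALSE)
  if (length(idx) == 0) return(empty)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6L)
  if (length(bad)) {
    stop(sprintf("%s line %d: expected >= 6 fields, found %d",
                 path, idx[bad[1]], nf[bad[1]]))
  }
  num <- function(k) suppressWarnings(as.integer(vapply(fields, `[[`, character(1), k)))
  out <- data.frame(
    dataset = dataset_name,
    chrom1 = vapply(fields, `[[`, character(1), 1L),
    start1 = num(2L), end1 = num(3L),
    chrom2 = vapply(fields, `[[`, character(1), 4L),
    start2 = num(5L), end2 = num(6L),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(out$start1) | is.na(out$end1) |
                 is.na(out$start2) | is.na(out$end2))
  if (length(bad)) {
    stop(sprintf("%s line %d: non-integer coordinates", path, idx[bad[1]]))
  }
  bad <- which(out$start1 > out$end1 | out$start2 > out$end2)
  if (length(bad)) {
    stop(sprintf("%s line %d: anchor start > end", path, idx[bad[1]]))
  }
  out
}

#' Write loops as BEDPE
#' @param loops Loop data frame as returned by [read_bedpe()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  stopifnot(all(cols %in% names(loops)))
  write.table(loops[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read motifs in JASPAR PFM text format
#'
#' Parses the JASPAR text dialects: a header line `>ID NAME` followed by
#' four rows of counts in A, C, G, T order, either bare numbers or the
#' bracketed style `A [ 4 0 ]`. Row letters, when present, determine row
#' assignment.
#'
#' @param path Path to a JASPAR-format PFM file (one or more motifs).
#' @param pseudocount,background Passed to [position_matrix()].
#' @return A named list of `PositionMatrix` objects (names = motif IDs).
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.01,
                            background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop(path, ": no '>' motif headers found")
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    header <- sub("^>\\s*", "", lines[heads[i]])
    toks <- strsplit(header, "\\s+")[[1]]
    motif_id <- toks[1]
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4L) {
      stop(path, ": motif ", motif_id, " must have exactly 4 count rows, found ",
           length(body))
    }
    letters_given <- grepl("^[ACGTacgt]([[:space:]]|\\[)", body)
    rows <- lapply(body, function(ln) {
      base <- NA_character_
      if (grepl("^[ACGTacgt]([[:space:]]|\\[)", ln)) {
        base <- toupper(substr(ln, 1, 1))
        ln <- sub("^[ACGTacgt]", "", ln)
      }
      ln <- gsub("[][]", " ", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (anyNA(vals)) stop(path, ": motif ", motif_id, ": non-numeric count")
      list(base = base, vals = vals)
    })
    lens <- vapply(rows, function(r) length(r$vals), integer(1))
    if (length(unique(lens)) != 1L) {
      stop(path, ": motif ", motif_id, ": rows of unequal length")
    }
    counts <- do.call(rbind, lapply(rows, `[[`, "vals"))
    if (all(letters_given)) {
      ord <- match(c("A", "C", "G", "T"), vapply(rows, `[[`, character(1), "base"))
      if (anyNA(ord)) stop(path, ": motif ", motif_id, ": missing A/C/G/T row")
      counts <- counts[ord, , drop = FALSE]
    }
    if (any(counts < 0)) stop(path, ": motif ", motif_id, ": negative count")
    out[[motif_id]] <- position_matrix(motif_id, counts,
                                       pseudocount = pseudocount,
                                       background = background)
  }
  out
}

#' Write motifs in JASPAR PFM text format
#' @param pms A list of `PositionMatrix` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(pms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (pm in pms) {
    writeLines(sprintf(">%s %s", pm$motif_id, pm$motif_id), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(pm$counts[b, ], trim = TRUE), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read a FASTA file as a named character vector of sequences
#'
#' Uses Biostrings for parsing; sequence names are truncated at the first
#' whitespace, matching common genome-FASTA conventions.
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector, one element per sequence.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a named character vector of sequences as FASTA
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Extract a subsequence using 0-based half-open coordinates
#'
#' @param genome Named character vector (see [read_fasta()]).
#' @param chrom Sequence name.
#' @param start,end 0-based half-open span.
#' @return Uppercase DNA string of length `end - start`.
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  n <- nchar(genome[[chrom]])
  if (start < 0 || end > n) {
    stop(sprintf("region %s:%d-%d outside sequence of length %d",
                 chrom, start, end, n))
  }
  toupper(substr(genome[[chrom]], start + 1L, end))
}

#' Report chromosome-name mismatches between tracks and a genome
#'
#' Chromosome names are matched as exact strings (no "chr" aliasing); this
#' validation surfaces silent mismatches before feature extraction.
#'
#' @param tracks A list of `TrackSet` objects.
#' @param genome Named character vector of sequences.
#' @return Data frame (track, chrom) of chromosome names present in a track
#'   but absent from the genome; zero rows if everything matches.
#' @export
validate_chromosomes <- function(tracks, genome) {
  out <- lapply(tracks, function(tr) {
    miss <- setdiff(unique(tr$intervals$chrom), names(genome))
    if (length(miss) == 0) return(NULL)
    data.frame(track = tr$name, chrom = miss, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(track = character(), chrom = character(),
                      stringsAsFactors = FALSE)
  }
  out
}
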