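# Per-base coverage tracks: a run-length encoded vector per chromosome plus
# the library size used for per-million scaling.

#' Construct a coverage track
#'
#' A `CoverageTrack` bundles per-base, nonnegative read counts (one
#' run-length encoded vector per chromosome) with the library size used for
#' per-million normalization and the factor/condition labels of the
#' experiment it came from.
#'
#' @param cov A named `RleList` (or named list of numeric vectors) of
#'   per-base counts, one element per chromosome.
#' @param library_size Total mapped reads. Defaults to the sum of the track,
#'   which is exact for coverage generated directly as counts.
#' @param factor,condition Labels (e.g. `"Pol2"`, `"U"`).
#' @return An object of class `CoverageTrack`.
#' @export
coverage_track <- function(cov, library_size = NULL,
                           factor = NA_character_, condition = NA_character_) {
  if (!is(cov, "RleList")) cov <- as(lapply(cov, Rle), "SimpleRleList")
  if (is.null(names(cov)) || any(!nzchar(names(cov)))) {
    stop("coverage chromosomes must be named")
  }
  if (any(vapply(cov, function(x) any(runValue(x) < 0), logical(1)))) {
    stop("coverage values must be nonnegative")
  }
  if (is.null(library_size)) library_size <- sum(as.numeric(sum(cov)))
  if (library_size <= 0) library_size <- 1
  structure(list(cov = cov, library_size = as.numeric(library_size),
                 factor = factor, condition = condition),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack: factor=%s condition=%s\n", x$factor, x$condition))
  cat(sprintf("  %d chromosome(s), library size %.0f\n",
              length(x$cov), x$library_size))
  invisible(x)
}

#' Chromosome lengths of a coverage track
#' @param track A `CoverageTrack`.
#' @return Named integer vector.
#' @export
track_lengths <- function(track) {
  setNames(lengths(track$cov), names(track$cov))
}

#' Sum coverage over regions
#'
#' Returns, per region, the sum of per-base counts over the region after
#' clipping it to the chromosome bounds, along with the clipped width so
#' densities can be computed over the bases actually summed. Degenerate
#' regions falling entirely off a chromosome get count 0 and width 0 rather
#' than an error; an unknown chromosome is an error.
#'
#' @param track A `CoverageTrack`.
#' @param regions A `GRanges`.
#' @return A `data.frame` with columns `count` and `width` (clipped width in
#'   bases), one row per region.
#' @export
count_reads <- function(track, regions) {
  chroms <- as.character(seqnames(regions))
  unknown <- setdiff(unique(chroms), names(track$cov))
  if (length(unknown)) {
    stop("unknown chromosome(s) in coverage track: ",
         paste(unknown, collapse = ", "))
  }
  n <- length(regions)
  count <- numeric(n)
  cwidth <- integer(n)
  lens <- track_lengths(track)
  s <- pmax(start(regions), 1L)
  e <- pmin(end(regions), lens[chroms])
  ok <- which(s <= e)
  if (length(ok)) {
    grp <- split(ok, chroms[ok])
    for (chrom in names(grp)) {
      idx <- grp[[chrom]]
      v <- Views(track$cov[[chrom]], start = s[idx], end = e[idx])
      count[idx] <- viewSums(v)
      cwidth[idx] <- e[idx] - s[idx] + 1L
    }
  }
  data.frame(count = count, width = cwidth)
}

#' Read a 4-column bedGraph into a coverage track
#'
#' bedGraph intervals are 0-based half-open; the imported values are
#' expanded to a per-base run-length vector per chromosome.
#'
#' @param path Path to a bedGraph file.
#' @param chrom_sizes Named vector of chromosome lengths (required so that
#'   trailing zero-coverage stretches are represented).
#' @param library_size,factor,condition Passed to [coverage_track()].
#' @return A `CoverageTrack`.
#' @export
read_bedgraph <- function(path, chrom_sizes, library_size = NULL,
                          factor = NA_character_, condition = NA_character_) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  seqlevels(gr) <- names(chrom_sizes)
  seqlengths(gr) <- chrom_sizes
  cov <- coverage(gr, weight = "score")
  coverage_track(cov, library_size = library_size,
                 factor = factor, condition = condition)
}

#' Write a coverage track as 4-column bedGraph
#'
#' Zero-coverage runs are omitted, as is conventional; coordinates are
#' written 0-based half-open.
#'
#' @param track A `CoverageTrack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$cov), function(chrom) {
    r <- track$cov[[chrom]]
    ends <- cumsum(runLength(r))
    starts <- ends - runLength(r) + 1L
    keep <- runValue(r) != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = chrom, start = starts[keep] - 1L, end = ends[keep],
               value = runValue(r)[keep])
  })
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                    end = integer(), value = numeric())
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
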