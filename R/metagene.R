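# TSS-anchored binned coverage matrices (heat maps) and mean profiles with
# SEM / 95% confidence bands.

#' Binned, TSS-anchored coverage matrix
#'
#' Extracts per-base coverage over `span` around each transcript's TSS in
#' transcript orientation (minus-strand rows are reversed so increasing x
#' is always downstream of the TSS), averages within `bin`-nt bins and
#' scales to per-million library units. Positions clipped at chromosome
#' edges contribute zeros; rows with any clipping are flagged.
#'
#' @param track A [coverage_track()].
#' @param tx A `GRanges` of transcript models (with seqlengths for edge
#'   clipping).
#' @param span Length-2 integer: offsets of the window relative to the TSS,
#'   default `c(-200, 1500)` (the TSS sits at offset 0; the window covers
#'   `span[1] .. span[2] - 1`).
#' @param bin Bin width in nt (default 10); must divide the span length.
#' @return A numeric matrix (rows = transcripts, named by `transcript_id`;
#'   columns = bins) with attributes `bin_centers` (offsets of bin centers
#'   from the TSS) and `clipped` (logical per row).
#' @export
binned_matrix <- function(track, tx, span = c(-200L, 1500L), bin = 10L) {
  span_len <- span[2] - span[1]
  if (span_len <= 0) stop("span must be increasing")
  if (span_len %% bin != 0) {
    stop("bin width ", bin, " does not divide span length ", span_len)
  }
  ncols <- span_len %/% bin
  plus <- as.character(strand(tx)) == "+"
  tss <- ifelse(plus, start(tx), end(tx))
  wstart <- ifelse(plus, tss + span[1], tss - span[2] + 1L)
  wend <- ifelse(plus, tss + span[2] - 1L, tss - span[1])
  lens <- track_lengths(track)
  chroms <- as.character(seqnames(tx))
  unknown <- setdiff(unique(chroms), names(lens))
  if (length(unknown)) {
    stop("unknown chromosome(s) in coverage track: ",
         paste(unknown, collapse = ", "))
  }
  scale <- 1e6 / track$library_size
  mat <- matrix(0, nrow = length(tx), ncol = ncols)
  clipped <- logical(length(tx))
  for (i in seq_along(tx)) {
    s <- wstart[i]; e <- wend[i]
    cs <- max(1L, s); ce <- min(lens[[chroms[i]]], e)
    v <- numeric(span_len)
    if (cs <= ce) {
      v[(cs - s + 1L):(ce - s + 1L)] <-
        as.numeric(window(track$cov[[chroms[i]]], cs, ce))
    }
    clipped[i] <- cs != s || ce != e
    if (!plus[i]) v <- rev(v)
    mat[i, ] <- colMeans(matrix(v, nrow = bin)) * scale
  }
  rownames(mat) <- tx$transcript_id
  attr(mat, "bin_centers") <- span[1] + (seq_len(ncols) - 0.5) * bin
  attr(mat, "clipped") <- clipped
  mat
}

#' Order metagene rows by pausing index, descending
#'
#' @param mat A [binned_matrix()] result.
#' @param results A [compute_pausing_index()] result covering the rows.
#' @return The matrix with rows reordered (a permutation; `Inf` PI sorts
#'   first, undefined last).
#' @export
order_by_pi <- function(mat, results) {
  pi <- results$pi[match(rownames(mat), results$transcript_id)]
  mat[order(pi, decreasing = TRUE, na.last = TRUE), , drop = FALSE]
}

#' Per-bin mean profile with SEM and confidence band
#'
#' Column means over the matrix rows with the standard error of the mean
#' and a t-based confidence interval (`mean ± t(1 - (1-level)/2, n-1) ×
#' SEM`); with a single row the SEM and interval are undefined.
#'
#' @param mat A [binned_matrix()] result (or any numeric matrix).
#' @param conf_level Confidence level (default 0.95).
#' @return A `data.frame` with `bin_center`, `mean`, `sem`, `ci_low`,
#'   `ci_high`.
#' @export
mean_profile <- function(mat, conf_level = 0.95) {
  if (!is.matrix(mat) || nrow(mat) == 0) stop("empty metagene matrix")
  n <- nrow(mat)
  mu <- colMeans(mat)
  if (n > 1) {
    sem <- apply(mat, 2, sd) / sqrt(n)
    tq <- qt(1 - (1 - conf_level) / 2, df = n - 1)
    lo <- mu - tq * sem
    hi <- mu + tq * sem
  } else {
    sem <- rep(NA_real_, length(mu))
    lo <- hi <- rep(NA_real_, length(mu))
  }
  centers <- attr(mat, "bin_centers")
  if (is.null(centers)) centers <- seq_along(mu)
  data.frame(bin_center = centers, mean = mu, sem = sem,
             ci_low = lo, ci_high = hi)
}

#' Shared display cap for heat-map scale equalization
#'
#' The stated percentile of the pooled nonzero values across the matrices;
#' values above the cap are meant to saturate in rendering only — the data
#' are untouched. All-zero input yields cap 0 with a warning.
#'
#' @param matrices A list of numeric matrices.
#' @param percentile Percentile in (0, 100] (default 99).
#' @return A single numeric cap.
#' @export
equalize_scales <- function(matrices, percentile = 99) {
  stopifnot(length(matrices) >= 1, percentile > 0, percentile <= 100)
  pool <- unlist(lapply(matrices, function(m) m[m != 0]), use.names = FALSE)
  if (length(pool) == 0) {
    warning("all matrices are zero; display cap set to 0")
    return(0)
  }
  # type 1 (inverse CDF): the cap is an order statistic of the pool
  quantile(pool, percentile / 100, names = FALSE, type = 1)
}
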