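# Pausing index: transcript collapsing by shared 5' ends, the promoter /
# gene-body log-density ratio, class assignment, the Pol2 promoter-peak
# eligibility filter, and gene-set cross-tabulation.

#' Parameters of the pausing-index statistic
#'
#' @param promoter_upstream,promoter_downstream Promoter window extents
#'   around the TSS (defaults -200/+500 in transcript orientation).
#' @param body_start Offset from the TSS at which the gene body begins
#'   (default +500); the body runs to the transcript 3' end.
#' @param paused_threshold PI above which a transcript is paused
#'   (default 1).
#' @param nonpaused_threshold PI below which it is non-paused (default
#'   0.8); values in between are ambiguous.
#' @param log_base Base of the logs in the ratio (default 2; the
#'   classification is invariant to this choice since the ratio of same-base
#'   logs cancels the base).
#' @param density_scale Scale densities to per-million library units before
#'   the log ratio (default `TRUE`).
#' @param pseudocount Added inside each log so the statistic is finite and
#'   sign-stable at low densities (default 1).
#' @param min_body_length Bodies shorter than this (after the `body_start`
#'   offset) make a transcript ineligible: densities over a tiny body are
#'   unstable (default 100 nt).
#' @return A list of class `pausing_params`.
#' @export
pausing_params <- function(promoter_upstream = 200L, promoter_downstream = 500L,
                           body_start = 500L, paused_threshold = 1.0,
                           nonpaused_threshold = 0.8, log_base = 2,
                           density_scale = TRUE, pseudocount = 1,
                           min_body_length = 100L) {
  p <- as.list(environment())
  stopifnot(p$nonpaused_threshold < p$paused_threshold,
            p$promoter_upstream + p$promoter_downstream > 0,
            p$log_base > 1, p$pseudocount >= 0)
  class(p) <- "pausing_params"
  p
}

#' Collapse transcripts sharing an identical 5' end into one gene model
#'
#' Transcripts are grouped by (chromosome, strand, TSS); each group is
#' replaced by a single model spanning the shared TSS to the farthest 3' end
#' in the group, keeping the lexicographically smallest transcript id as the
#' representative. Groups of one pass through unchanged. The operation is
#' idempotent.
#'
#' @param tx A `GRanges` of transcript models with `transcript_id` and
#'   `gene_id` columns.
#' @return A `GRanges` with one model per distinct 5' end, plus an
#'   `n_collapsed` column.
#' @export
collapse_transcripts <- function(tx) {
  if (length(tx) == 0) return(tx)
  stopifnot(all(as.character(strand(tx)) %in% c("+", "-")))
  plus <- as.character(strand(tx)) == "+"
  tss <- ifelse(plus, start(tx), end(tx))
  key <- paste(as.character(seqnames(tx)), as.character(strand(tx)), tss)
  idx <- split(seq_along(tx), key)
  rows <- lapply(idx, function(i) {
    g <- tx[i]
    rep_id <- sort(g$transcript_id)[1]
    i_plus <- as.character(strand(g)[1]) == "+"
    s <- if (i_plus) start(g)[1] else min(start(g))
    e <- if (i_plus) max(end(g)) else end(g)[1]
    data.frame(chrom = as.character(seqnames(g)[1]), start = s, end = e,
               strand = as.character(strand(g)[1]), transcript_id = rep_id,
               gene_id = g$gene_id[1], n_collapsed = length(i))
  })
  df <- do.call(rbind, rows)
  out <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                 transcript_id = df$transcript_id, gene_id = df$gene_id,
                 n_collapsed = df$n_collapsed)
  seqlevels(out) <- seqlevels(tx)
  seqlengths(out) <- seqlengths(tx)
  sort(out, ignore.strand = TRUE)
}

#' Compute per-transcript pausing indices
#'
#' For each transcript the promoter window (-200/+500 around the TSS by
#' default) and gene body (+500 to the 3' end) are summed from the coverage
#' track, converted to per-base densities over the clipped window lengths,
#' scaled to per-million library units, and combined as
#' `PI = log(1 + d_promoter) / log(1 + d_body)`. A zero body with a nonzero
#' promoter gives `PI = Inf` (paused); both windows zero give an undefined
#' PI and class. Transcripts whose body is shorter than
#' `params$min_body_length` are marked ineligible rather than erroring.
#'
#' @param track A [coverage_track()] (conventionally Pol2 in the untreated
#'   condition, the state in which pausing is defined).
#' @param tx A `GRanges` of (collapsed) transcript models.
#' @param params A [pausing_params()] list.
#' @return A `data.frame` with one row per transcript: windows, raw counts,
#'   densities, `pi`, `pi_class` and `eligible` (body-length filter only;
#'   see [filter_by_promoter_peaks()] for the peak filter).
#' @export
compute_pausing_index <- function(track, tx, params = pausing_params()) {
  p <- params
  prom <- promoter_window(tx, p$promoter_upstream, p$promoter_downstream)
  body <- body_window(tx, p$body_start)
  prom_c <- count_reads(track, prom)
  body_c <- count_reads(track, body)
  scale <- if (p$density_scale) 1e6 / track$library_size else 1
  d_p <- ifelse(prom_c$width > 0, prom_c$count / prom_c$width, 0) * scale
  d_b <- ifelse(body_c$width > 0, body_c$count / body_c$width, 0) * scale
  num <- log(p$pseudocount + d_p, base = p$log_base)
  den <- log(p$pseudocount + d_b, base = p$log_base)
  pi_val <- ifelse(den > 0, num / den,
                   ifelse(num > 0, Inf, NA_real_))
  eligible <- body$valid & body_c$width >= p$min_body_length
  res <- data.frame(
    transcript_id = tx$transcript_id, gene_id = tx$gene_id,
    chrom = as.character(seqnames(tx)), strand = as.character(strand(tx)),
    promoter_start = start(prom), promoter_end = end(prom),
    body_start = start(body), body_end = end(body),
    promoter_count = prom_c$count, body_count = body_c$count,
    promoter_density = d_p, body_density = d_b,
    pi = pi_val,
    pi_class = classify_pi(pi_val, p),
    eligible = eligible,
    stringsAsFactors = FALSE)
  attr(res, "params") <- p
  res
}

#' Classify pausing-index values
#'
#' `PI > paused_threshold` is paused; `PI < nonpaused_threshold` is
#' non-paused; values between the thresholds (inclusive) are ambiguous and
#' belong to neither class; `NA` (both windows empty) is undefined.
#'
#' @param pi Numeric vector of PI values (may contain `Inf` and `NA`).
#' @param params A [pausing_params()] list.
#' @return Character vector: `paused`, `non_paused`, `ambiguous`,
#'   `undefined`.
#' @export
classify_pi <- function(pi, params = pausing_params()) {
  out <- rep("ambiguous", length(pi))
  out[pi > params$paused_threshold] <- "paused"
  out[pi < params$nonpaused_threshold] <- "non_paused"
  out[is.na(pi)] <- "undefined"
  out
}

#' Flag transcripts whose promoter overlaps a Pol2 peak
#'
#' Eligibility for heat maps and class tallies requires the promoter window
#' to overlap (>= 1 nt) a Pol2 peak called in the LPS-treated condition;
#' ineligible transcripts are retained but flagged. The flag is combined
#' (AND) with the body-length eligibility already present.
#'
#' @param results A [compute_pausing_index()] result.
#' @param pol2_peaks A `GRanges` of Pol2 peaks (conventionally from the
#'   LPS condition).
#' @param min_overlap Minimum shared bases (default 1).
#' @return `results` with its `eligible` column updated.
#' @export
filter_by_promoter_peaks <- function(results, pol2_peaks, min_overlap = 1L) {
  prom <- GRanges(results$chrom,
                  IRanges(results$promoter_start, results$promoter_end))
  hit <- overlapsAny(prom, pol2_peaks, minoverlap = min_overlap,
                     ignore.strand = TRUE)
  results$eligible <- results$eligible & hit
  results
}

#' Cross-tabulate pausing classes within a gene set
#'
#' Counts eligible transcripts of the set in each pausing class, plus the
#' `PI > nonpaused_threshold` tally (the "not non-paused" margin used when
#' cross-tabulating knockout-upregulated genes against pausing state).
#'
#' @param gene_ids Character vector of member gene ids (a gene set).
#' @param results A (filtered) [compute_pausing_index()] result.
#' @return A list with `counts` (named: paused, non_paused, ambiguous,
#'   undefined), `fractions` (of defined, eligible transcripts; `NA` when
#'   none), `n_eligible` and `n_pi_above_nonpaused`.
#' @export
crosstab_pi <- function(gene_ids, results) {
  sel <- results[results$gene_id %in% gene_ids & results$eligible, ,
                 drop = FALSE]
  classes <- c("paused", "non_paused", "ambiguous", "undefined")
  counts <- setNames(vapply(classes, function(cl)
    sum(sel$pi_class == cl), integer(1)), classes)
  n_def <- sum(counts[c("paused", "non_paused", "ambiguous")])
  fractions <- if (n_def > 0) counts[1:3] / n_def else
    setNames(rep(NA_real_, 3), classes[1:3])
  thr <- attr(results, "params")
  thr <- if (!is.null(thr)) thr$nonpaused_threshold else 0.8
  list(counts = counts, fractions = fractions, n_eligible = nrow(sel),
       n_pi_above_nonpaused = sum(sel$pi > thr, na.rm = TRUE))
}

#' Write a pausing-index table and promoter BED
#'
#' @param results A [compute_pausing_index()] result.
#' @param tsv_path Path for the per-transcript TSV.
#' @param bed_path Optional path for a BED6 of promoter windows with the PI
#'   as score.
#' @return `tsv_path`, invisibly.
#' @export
write_pausing_table <- function(results, tsv_path, bed_path = NULL) {
  write.table(results, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(bed_path)) {
    gr <- GRanges(results$chrom,
                  IRanges(results$promoter_start, results$promoter_end),
                  strand = results$strand, name = results$transcript_id,
                  score = ifelse(is.finite(results$pi), results$pi, 0))
    write_peaks(gr, bed_path, "BED6")
  }
  invisible(tsv_path)
}
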