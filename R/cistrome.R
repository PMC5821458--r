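# Cistrome operations: replicate unions, Venn partitions by overlap,
# genomic-feature annotation of peaks, gene-window association, and
# class-conditional promoter-occupancy fractions.

#' Union of two peak replicates
#'
#' Pools the two sets and merges overlapping or bookended (gap 0) intervals
#' into single peaks. The summit of a merged peak is inherited from its
#' widest contributor (offset recomputed relative to the merged start).
#' Commutative and idempotent.
#'
#' @param rep1,rep2 Peak `GRanges` (as from [read_peaks()] or
#'   [generate_peaks()]); factor/condition labels in `metadata()`, when
#'   present on both, must agree.
#' @return A merged `GRanges` with a `summit` column.
#' @export
union_replicates <- function(rep1, rep2) {
  m1 <- metadata(rep1); m2 <- metadata(rep2)
  for (lab in c("factor", "condition")) {
    a <- m1[[lab]]; b <- m2[[lab]]
    if (!is.null(a) && !is.null(b) && !is.na(a) && !is.na(b) &&
        !identical(a, b)) {
      stop(lab, " mismatch between replicates: ", a, " vs ", b)
    }
  }
  pooled <- c(granges(rep1), granges(rep2))
  strand(pooled) <- "*"
  merged <- reduce(pooled, min.gapwidth = 1L)
  # carry the widest contributor's summit into each merged peak
  contrib <- c(rep1, rep2)
  if (length(contrib) && !is.null(contrib$summit)) {
    hits <- findOverlaps(merged, contrib, ignore.strand = TRUE)
    widest <- tapply(subjectHits(hits), queryHits(hits), function(j) {
      j[which.max(width(contrib)[j])]
    })
    qi <- as.integer(names(widest))
    abs_summit <- start(contrib)[unlist(widest)] +
      contrib$summit[unlist(widest)]
    merged$summit <- NA_integer_
    merged$summit[qi] <- as.integer(abs_summit - start(merged)[qi])
  }
  metadata(merged) <- list(
    factor = if (!is.null(m1$factor) && !is.na(m1$factor)) m1$factor
    else m2$factor,
    condition = if (!is.null(m1$condition) && !is.na(m1$condition))
      m1$condition else m2$condition,
    replicate = NA_integer_)
  sort(merged, ignore.strand = TRUE)
}

#' Venn partition of two peak sets by overlap
#'
#' Splits each set into peaks that do and do not overlap (>= `min_overlap`
#' shared bases, strand ignored) the other set. The shared counts are
#' asymmetric by design: `shared_a` counts A peaks overlapping at least one
#' B peak and `shared_b` the converse, and the two differ under
#' many-to-one overlaps. Conservation (`unique + shared = total`) holds on
#' each side.
#'
#' @param a,b Peak `GRanges`.
#' @param min_overlap Minimum shared bases (default 1).
#' @param label_a,label_b Display labels.
#' @return A list of class `venn_partition` with counts (`total_a`,
#'   `shared_a`, `unique_a`, and the `_b` mirrors) and the four interval
#'   sets.
#' @export
venn_partition <- function(a, b, min_overlap = 1L,
                           label_a = "A", label_b = "B") {
  in_b <- overlapsAny(a, b, minoverlap = min_overlap, ignore.strand = TRUE)
  in_a <- overlapsAny(b, a, minoverlap = min_overlap, ignore.strand = TRUE)
  structure(list(
    label_a = label_a, label_b = label_b,
    total_a = length(a), total_b = length(b),
    shared_a = sum(in_b), shared_b = sum(in_a),
    unique_a = sum(!in_b), unique_b = sum(!in_a),
    shared_a_peaks = a[in_b], unique_a_peaks = a[!in_b],
    shared_b_peaks = b[in_a], unique_b_peaks = b[!in_a]),
    class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("venn_partition: %s (%d) vs %s (%d)\n",
              x$label_a, x$total_a, x$label_b, x$total_b))
  cat(sprintf("  %s: %d shared + %d unique\n", x$label_a, x$shared_a,
              x$unique_a))
  cat(sprintf("  %s: %d shared + %d unique\n", x$label_b, x$shared_b,
              x$unique_b))
  invisible(x)
}

#' Annotate peaks relative to genomic features
#'
#' Each peak is assigned exactly one category from its summit position
#' (midpoint when no summit is recorded) with precedence promoter > exon >
#' intron > downstream > distal_intergenic. The promoter is
#' `-promoter_up/+promoter_down` around a TSS in transcript orientation
#' (wider than the pausing-index window, matching common annotation
#' practice); downstream is up to `downstream_max` past a 3' end. Without
#' exon structure the whole gene span counts as exonic and intron is
#' unavailable (noted in the `intron_available` attribute). The signed
#' distance from the summit to the nearest TSS is negative 5' of the TSS.
#'
#' @param peaks Peak `GRanges`.
#' @param tx Transcript models (`GRanges` with `gene_id`).
#' @param exons Optional `GRanges` of exons with a `gene_id` column.
#' @param promoter_up,promoter_down Promoter window (defaults 2000/500).
#' @param downstream_max Downstream window past the 3' end (default 1000).
#' @return A `data.frame` with `category`, `nearest_gene` and
#'   `tss_distance`, one row per peak.
#' @export
annotate_features <- function(peaks, tx, exons = NULL,
                              promoter_up = 2000L, promoter_down = 500L,
                              downstream_max = 1000L) {
  n <- length(peaks)
  pos <- if (!is.null(peaks$summit) && !all(is.na(peaks$summit))) {
    ifelse(is.na(peaks$summit), start(peaks) + width(peaks) %/% 2L,
           start(peaks) + peaks$summit)
  } else start(peaks) + width(peaks) %/% 2L
  pts <- GRanges(seqnames(peaks), IRanges(pos, pos))

  tss_gr <- resize(tx, 1L, fix = "start")
  prom <- promoter_window(tx, promoter_up, promoter_down)
  plus <- as.character(strand(tx)) == "+"
  down <- GRanges(seqnames(tx),
                  IRanges(ifelse(plus, end(tx) + 1L,
                                 pmax(1L, start(tx) - downstream_max)),
                          ifelse(plus, end(tx) + downstream_max,
                                 pmax(1L, start(tx) - 1L))))

  in_prom <- overlapsAny(pts, prom, ignore.strand = TRUE)
  in_gene <- overlapsAny(pts, tx, ignore.strand = TRUE)
  if (!is.null(exons)) {
    in_exon <- in_gene & overlapsAny(pts, exons, ignore.strand = TRUE)
    in_intron <- in_gene & !in_exon
  } else {
    in_exon <- in_gene
    in_intron <- rep(FALSE, n)
  }
  in_down <- overlapsAny(pts, down, ignore.strand = TRUE)

  category <- rep("distal_intergenic", n)
  category[in_down] <- "downstream"
  category[in_intron] <- "intron"
  category[in_exon] <- "exon"
  category[in_prom] <- "promoter"

  nearest_idx <- nearest(pts, tss_gr, ignore.strand = TRUE)
  tss_pos <- start(tss_gr)[nearest_idx]
  sign_flip <- ifelse(as.character(strand(tx))[nearest_idx] == "+", 1L, -1L)
  tss_distance <- (pos - tss_pos) * sign_flip
  out <- data.frame(category = category,
                    nearest_gene = tx$gene_id[nearest_idx],
                    tss_distance = tss_distance,
                    stringsAsFactors = FALSE)
  attr(out, "intron_available") <- !is.null(exons)
  out
}

#' Associate peaks with genes through a flanked window
#'
#' A peak is associated with a gene when it overlaps (>= 1 nt) the window
#' spanning the gene plus `flank` bases on each side; a peak may associate
#' with several genes and every association is reported.
#'
#' @param peaks Peak `GRanges`.
#' @param genes Gene/transcript models (`GRanges` with `gene_id`).
#' @param flank Flank size in bases (default 100 kb).
#' @return A `data.frame` with `gene_id` and `peak_index` (position in
#'   `peaks`).
#' @export
gene_window_association <- function(peaks, genes, flank = 100000L) {
  stopifnot(flank >= 0)
  win <- clip_to_chrom(suppressWarnings(genes + flank))
  hits <- findOverlaps(peaks, win, ignore.strand = TRUE)
  data.frame(gene_id = genes$gene_id[subjectHits(hits)],
             peak_index = queryHits(hits),
             stringsAsFactors = FALSE)
}

#' Promoter-occupancy fraction of a gene class
#'
#' The fraction of class members whose promoter window overlaps at least
#' one peak, with an exact (Clopper-Pearson) binomial confidence interval.
#'
#' @param gene_ids Character vector of class member gene ids.
#' @param results A [compute_pausing_index()] result (provides promoter
#'   windows per transcript); only eligible transcripts are counted and each
#'   gene contributes once (occupied if any of its transcripts' promoters
#'   is).
#' @param peaks Peak `GRanges` (e.g. NELF in one condition).
#' @param min_overlap Minimum shared bases (default 1).
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return A list: `k` occupied, `n` class size, `fraction`, `ci_low`,
#'   `ci_high`. `n = 0` gives an `NA` fraction with a warning.
#' @export
promoter_occupancy_fraction <- function(gene_ids, results, peaks,
                                        min_overlap = 1L, conf_level = 0.95) {
  sel <- results[results$gene_id %in% gene_ids & results$eligible, ,
                 drop = FALSE]
  genes <- unique(sel$gene_id)
  n <- length(genes)
  if (n == 0) {
    warning("empty gene class: occupancy fraction undefined")
    return(list(k = 0L, n = 0L, fraction = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_))
  }
  prom <- GRanges(sel$chrom, IRanges(sel$promoter_start, sel$promoter_end))
  hit <- overlapsAny(prom, peaks, minoverlap = min_overlap,
                     ignore.strand = TRUE)
  occupied <- tapply(hit, sel$gene_id, any)[genes]
  k <- sum(occupied)
  ci <- binom.test(k, n, conf.level = conf_level)$conf.int
  list(k = as.integer(k), n = n, fraction = k / n,
       ci_low = ci[1], ci_high = ci[2])
}
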