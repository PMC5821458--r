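suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# A transcript GRanges from 0-based half-open coordinates (BED-style), the
# convention used in hand-worked examples; converted here once so tests
# read like the examples.
tx_from_bed <- function(chrom, start0, end0, strand, id = NULL,
                        gene = NULL, chrom_len = NA_integer_) {
  n <- length(start0)
  if (is.null(id)) id <- paste0("T", seq_len(n))
  if (is.null(gene)) gene <- paste0("G", seq_len(n))
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand,
                transcript_id = id, gene_id = gene)
  if (!is.na(chrom_len)) {
    GenomeInfoDb::seqlengths(gr) <-
      setNames(rep(chrom_len, length(GenomeInfoDb::seqlevels(gr))),
               GenomeInfoDb::seqlevels(gr))
  }
  gr
}

# Peaks from 0-based half-open coordinates.
peaks_from_bed <- function(chrom, start0, end0) {
  GRanges(chrom, IRanges(start0 + 1L, end0))
}

# Random unstranded intervals on one small chromosome.
random_intervals <- function(n, max_pos = 1000L, max_len = 60L) {
  s <- sample.int(max_pos, n, replace = TRUE)
  GRanges("chr1", IRanges(s, s + sample.int(max_len, n, replace = TRUE)))
}

# O(n^2) reference: which intervals of a overlap >= min_overlap bases of
# any interval in b (1-based closed arithmetic, independent of GRanges).
brute_overlaps_any <- function(a, b, min_overlap = 1L) {
  vapply(seq_along(a), function(i) {
    any(vapply(seq_along(b), function(j) {
      as.character(seqnames(a)[i]) == as.character(seqnames(b)[j]) &&
        (min(end(a)[i], end(b)[j]) - max(start(a)[i], start(b)[j]) + 1L) >=
          min_overlap
    }, logical(1)))
  }, logical(1))
}
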