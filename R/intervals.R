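# Interval I/O and primitive overlap/window operations. Intervals live in
# GRanges (1-based closed); BED-family files are 0-based half-open on disk
# and converted at the boundary.

#' Read a BED6 or narrowPeak file into a GRanges
#'
#' Coordinates are converted from BED's 0-based half-open convention to the
#' 1-based closed convention of `GRanges`. For narrowPeak input the 10th
#' column is stored as a `summit` metadata column (offset in bases relative
#' to the peak start); a value of -1 (no summit called) is stored as `NA`.
#'
#' @param path Path to the file.
#' @param format `"BED6"` or `"narrowPeak"` (ENCODE 10-column).
#' @param factor,condition,replicate Optional labels attached to the result
#'   via `metadata()`, identifying the ChIP factor, treatment condition and
#'   replicate the peaks belong to.
#' @return A `GRanges` with `name` and `score` metadata columns (plus
#'   `summit`, `signalValue`, `pValue`, `qValue` for narrowPeak).
#' @export
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tp1\t0\t+", p)
#' read_peaks(p, "BED6")
read_peaks <- function(path, format = c("narrowPeak", "BED6"),
                       factor = NA_character_, condition = NA_character_,
                       replicate = NA_integer_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  ncol_expected <- if (format == "BED6") 6L else 10L
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    gr <- GRanges()
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf < ncol_expected)
    if (length(bad)) {
      stop(sprintf("%s parse error at line %d: expected %d fields, found %d",
                   format, bad[1], ncol_expected, nf[bad[1]]))
    }
    m <- do.call(rbind, fields)
    start0 <- suppressWarnings(as.numeric(m[, 2]))
    end0 <- suppressWarnings(as.numeric(m[, 3]))
    bad <- which(is.na(start0) | is.na(end0))
    if (length(bad)) stop(sprintf("%s parse error at line %d: non-numeric coordinates",
                                  format, bad[1]))
    bad <- which(start0 >= end0)
    if (length(bad)) {
      stop(sprintf("invalid interval at line %d: start (%s) >= end (%s)",
                   bad[1], m[bad[1], 2], m[bad[1], 3]))
    }
    strand <- m[, 6]
    strand[!strand %in% c("+", "-")] <- "*"
    gr <- GRanges(m[, 1], IRanges(start0 + 1L, end0), strand = strand,
                  name = m[, 4],
                  score = suppressWarnings(as.numeric(m[, 5])))
    if (format == "narrowPeak") {
      summit <- suppressWarnings(as.integer(m[, 10]))
      bad <- which(!is.na(summit) & summit >= 0L & summit >= width(gr))
      if (length(bad)) {
        stop(sprintf("invalid summit offset at line %d: %d >= peak width %d",
                     bad[1], summit[bad[1]], width(gr)[bad[1]]))
      }
      summit[!is.na(summit) & summit < 0L] <- NA_integer_
      gr$signalValue <- suppressWarnings(as.numeric(m[, 7]))
      gr$pValue <- suppressWarnings(as.numeric(m[, 8]))
      gr$qValue <- suppressWarnings(as.numeric(m[, 9]))
      gr$summit <- summit
    }
    gr <- sort(gr, ignore.strand = TRUE)
  }
  metadata(gr) <- list(factor = factor, condition = condition,
                       replicate = replicate)
  gr
}

#' Write a GRanges as BED6 or narrowPeak
#'
#' The inverse of [read_peaks()]: coordinates are converted back to 0-based
#' half-open, missing summits are written as -1, and unstranded intervals as
#' `.`.
#'
#' @param gr A `GRanges`; `name`/`score` metadata columns are used when
#'   present.
#' @param path Output path.
#' @param format `"BED6"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(gr, path, format = c("narrowPeak", "BED6")) {
  format <- match.arg(format)
  nm <- if (!is.null(gr$name)) gr$name else paste0("peak_", seq_along(gr))
  sc <- if (!is.null(gr$score)) gr$score else 0
  strand <- as.character(strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = nm, score = sc, strand = strand)
  if (format == "narrowPeak") {
    df$signalValue <- if (!is.null(gr$signalValue)) gr$signalValue else 0
    df$pValue <- if (!is.null(gr$pValue)) gr$pValue else -1
    df$qValue <- if (!is.null(gr$qValue)) gr$qValue else -1
    summit <- if (!is.null(gr$summit)) gr$summit else NA_integer_
    summit[is.na(summit)] <- -1L
    df$summit <- summit
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Keeps `transcript` records and returns them as a `GRanges` with
#' `transcript_id` and `gene_id` metadata columns. GTF coordinates are
#' 1-based inclusive, matching `GRanges` directly. Records without a strand
#' are dropped with a warning; duplicated transcript ids are an error. The
#' strand-aware TSS of each model is `start` on `+` and `end` on `-`.
#'
#' @param path Path to a GTF file.
#' @param chrom_sizes Optional named vector of chromosome lengths attached
#'   as `seqlengths` (used for clipping windows at chromosome ends).
#' @return A `GRanges` of transcript models.
#' @export
read_transcripts <- function(path, chrom_sizes = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "transcript"]
  unstranded <- as.character(strand(gr)) == "*"
  if (any(unstranded)) {
    warning(sum(unstranded), " transcript record(s) without strand dropped")
    gr <- gr[!unstranded]
  }
  if (anyDuplicated(gr$transcript_id)) {
    dup <- gr$transcript_id[duplicated(gr$transcript_id)][1]
    stop("duplicate transcript_id in ", path, ": ", dup)
  }
  mcols(gr) <- mcols(gr)[, c("transcript_id", "gene_id")]
  if (!is.null(chrom_sizes)) {
    seqlevels(gr) <- names(chrom_sizes)
    seqlengths(gr) <- chrom_sizes
  }
  sort(gr, ignore.strand = TRUE)
}

#' Write transcript models as GTF
#'
#' @param tx A `GRanges` with `transcript_id` and `gene_id` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(tx, path) {
  tx$type <- "transcript"
  tx$source <- "grpause"
  rtracklayer::export(tx, path, format = "gtf")
  invisible(path)
}

#' Pairwise interval overlap with a minimum shared length
#'
#' Two intervals overlap when they share at least `min_overlap` bases on the
#' same chromosome; strand is ignored (ChIP peaks are unstranded, and
#' standard cistrome overlap calls do not filter by strand). Adjacent
#' (bookended) intervals share zero bases and do not overlap.
#'
#' @param a,b `GRanges` objects, recycled like arithmetic operands when one
#'   has length 1.
#' @param min_overlap Minimum number of shared bases (default 1).
#' @return Logical vector.
#' @export
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 150))
#' interval_overlaps(a, b)            # TRUE: base 100 is shared
interval_overlaps <- function(a, b, min_overlap = 1L) {
  stopifnot(min_overlap >= 1L)
  if (length(a) == 1L && length(b) > 1L) a <- rep(a, length(b))
  if (length(b) == 1L && length(a) > 1L) b <- rep(b, length(a))
  stopifnot(length(a) == length(b))
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  shared <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  same & shared >= min_overlap
}

#' Strand-aware promoter window around a transcript's TSS
#'
#' Returns the window spanning `upstream` bases 5' of the TSS and
#' `downstream` bases from the TSS in the direction of transcription
#' (the TSS base itself is the first downstream base), so the window length
#' is `upstream + downstream` absent clipping. Windows running off
#' chromosome ends are clipped when `seqlengths` are available.
#'
#' @param tx A stranded `GRanges` of transcript models.
#' @param upstream,downstream Window extents in bases (defaults 200 and 500,
#'   the promoter-proximal window used by the pausing index).
#' @return A `GRanges` of promoter windows, same length and order as `tx`.
#' @export
promoter_window <- function(tx, upstream = 200L, downstream = 500L) {
  stopifnot(all(as.character(strand(tx)) %in% c("+", "-")))
  # out-of-bound windows are expected at chromosome edges; clipped below
  w <- suppressWarnings(promoters(tx, upstream = upstream,
                                  downstream = downstream))
  clip_to_chrom(w)
}

#' Gene-body window of a transcript (downstream of the pause region)
#'
#' The body runs from `body_start` bases past the TSS (in transcript
#' orientation) to the transcript's 3' end. Transcripts shorter than
#' `body_start` yield a zero-width placeholder flagged by a `valid = FALSE`
#' metadata column.
#'
#' @param tx A stranded `GRanges` of transcript models.
#' @param body_start Offset from the TSS at which the body begins
#'   (default 500).
#' @return A `GRanges` with a `valid` metadata column.
#' @export
body_window <- function(tx, body_start = 500L) {
  stopifnot(all(as.character(strand(tx)) %in% c("+", "-")))
  plus <- as.character(strand(tx)) == "+"
  valid <- width(tx) > body_start
  bstart <- ifelse(plus, start(tx) + body_start, start(tx))
  bend <- ifelse(plus, end(tx), end(tx) - body_start)
  bad <- !valid
  bstart[bad] <- start(tx)[bad]
  bend[bad] <- start(tx)[bad]
  out <- GRanges(seqnames(tx), IRanges(bstart, bend), strand = strand(tx),
                 valid = valid, seqinfo = seqinfo(tx))
  out
}

# Clip ranges to [1, seqlength]; ranges on chromosomes without a known
# length are only clipped at 1.
clip_to_chrom <- function(gr) {
  sl <- seqlengths(gr)
  newstart <- pmax(start(gr), 1L)
  newend <- end(gr)
  if (length(sl) && !all(is.na(sl))) {
    lim <- sl[as.character(seqnames(gr))]
    has <- !is.na(lim)
    newend[has] <- pmin(newend[has], lim[has])
  }
  ranges(gr) <- IRanges(newstart, pmax(newend, newstart))
  gr
}

#' Read a two-column chromosome-sizes file
#'
#' @param path TSV with columns chromosome name and length.
#' @return Named integer vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "size"),
                   colClasses = c("character", "integer"))
  setNames(df$size, df$chrom)
}
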