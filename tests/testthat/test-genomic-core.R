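# Interval I/O, overlap primitives, window arithmetic and coverage sums.

test_that("BED6 and narrowPeak read/write round-trip preserves all fields", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tp1\t5\t+",
               "chr2\t0\t50\tp2\t0\t-",
               "chr1\t300\t400\tp3\t1\t."), bed)
  gr <- read_peaks(bed, "BED6")
  expect_equal(start(gr), c(101L, 301L, 1L))
  expect_equal(end(gr), c(200L, 400L, 50L))
  expect_equal(gr$name, c("p1", "p3", "p2"))
  out <- tempfile(fileext = ".bed")
  write_peaks(gr, out, "BED6")
  gr2 <- read_peaks(out, "BED6")
  expect_identical(as.character(seqnames(gr)), as.character(seqnames(gr2)))
  expect_identical(ranges(gr), ranges(gr2))
  expect_identical(gr$name, gr2$name)
  expect_identical(gr$score, gr2$score)
  expect_identical(as.character(strand(gr)), as.character(strand(gr2)))

  np <- tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t200\tp1\t0\t.\t4.5\t-1\t-1\t50",
               "chr1\t500\t700\tp2\t0\t.\t2.0\t-1\t-1\t-1"), np)
  gp <- read_peaks(np, "narrowPeak")
  expect_equal(gp$summit, c(50L, NA_integer_))
  out2 <- tempfile(fileext = ".narrowPeak")
  write_peaks(gp, out2, "narrowPeak")
  gp2 <- read_peaks(out2, "narrowPeak")
  expect_identical(ranges(gp), ranges(gp2))
  expect_identical(gp$summit, gp2$summit)
  expect_identical(gp$signalValue, gp2$signalValue)
})

test_that("malformed peak files fail with the offending line number", {
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tok\t0\t+", "chr1\t200\t100\tbad\t0\t+"), bad)
  expect_error(read_peaks(bad, "BED6"), "line 2")
  short <- tempfile(fileext = ".bed")
  writeLines("chr1\t100", short)
  expect_error(read_peaks(short, "BED6"), "line 1")
})

test_that("GTF transcripts convert coordinates and TSS by strand", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\ttranscript\t1001\t2000\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\tsrc\ttranscript\t1001\t2000\t.\t-\t.\t",
           'gene_id "g2"; transcript_id "t2";')), gtf)
  tx <- read_transcripts(gtf)
  tx <- tx[match(c("t1", "t2"), tx$transcript_id)]
  # GTF 1001..2000 is 0-based [1000, 2000); GRanges keeps 1001..2000
  expect_equal(start(tx), c(1001L, 1001L))
  expect_equal(end(tx), c(2000L, 2000L))
  tss0 <- ifelse(as.character(strand(tx)) == "+", start(tx), end(tx)) - 1L
  # 0-based TSS: 1000 on the + strand, 1999 on the - strand
  expect_equal(tss0, c(1000L, 1999L))

  dup <- tempfile(fileext = ".gtf")
  writeLines(rep(paste0("chr1\tsrc\ttranscript\t1\t100\t.\t+\t.\t",
                        'gene_id "g"; transcript_id "t";'), 2), dup)
  expect_error(read_transcripts(dup), "duplicate transcript_id")

  nostrand <- tempfile(fileext = ".gtf")
  writeLines(c(paste0("chr1\tsrc\ttranscript\t1\t100\t.\t.\t.\t",
                      'gene_id "g"; transcript_id "t0";'),
               paste0("chr1\tsrc\ttranscript\t1\t100\t.\t+\t.\t",
                      'gene_id "g"; transcript_id "t1";')), nostrand)
  expect_warning(tx2 <- read_transcripts(nostrand), "without strand")
  expect_equal(tx2$transcript_id, "t1")
})

test_that("interval overlap honors the minimum shared-base threshold", {
  # 0-based [0,100) vs [99,150): one shared base
  expect_true(interval_overlaps(peaks_from_bed("chr1", 0, 100),
                                peaks_from_bed("chr1", 99, 150)))
  # half-open adjacency shares nothing
  expect_false(interval_overlaps(peaks_from_bed("chr1", 0, 100),
                                 peaks_from_bed("chr1", 100, 150)))
  # [0,100) vs [95,150): 5 shared bases, below a 10-base minimum
  expect_false(interval_overlaps(peaks_from_bed("chr1", 0, 100),
                                 peaks_from_bed("chr1", 95, 150),
                                 min_overlap = 10))
  expect_true(interval_overlaps(peaks_from_bed("chr1", 0, 100),
                                peaks_from_bed("chr1", 95, 150),
                                min_overlap = 5))
  # different chromosomes never overlap
  expect_false(interval_overlaps(peaks_from_bed("chr1", 0, 100),
                                 peaks_from_bed("chr2", 0, 100)))
})

test_that("interval overlap is symmetric for every minimum", {
  set.seed(101)
  for (mo in c(1L, 5L, 20L)) {
    a <- random_intervals(40)
    b <- random_intervals(40)
    expect_identical(interval_overlaps(a, b, mo), interval_overlaps(b, a, mo))
  }
})

test_that("count_reads sums coverage, clips at edges and is additive", {
  trk <- coverage_track(list(chr1 = rep(2, 100)), library_size = 1000)
  # constant coverage 2 over 0-based [10,20): 10 bases
  r <- count_reads(trk, peaks_from_bed("chr1", 10, 20))
  expect_equal(r$count, 20)
  expect_equal(r$width, 10L)
  # empty (all-zero) track
  z <- coverage_track(list(chr1 = rep(0, 50)), library_size = 1)
  expect_equal(count_reads(z, peaks_from_bed("chr1", 0, 50))$count, 0)
  # clipping past the chromosome end
  rc <- count_reads(trk, peaks_from_bed("chr1", 90, 150))
  expect_equal(rc$width, 10L)
  expect_equal(rc$count, 20)
  # unknown chromosome errors
  expect_error(count_reads(trk, peaks_from_bed("chrX", 0, 10)),
               "unknown chromosome")

  # random track: window sum equals a per-base loop, and is additive over
  # a partition
  set.seed(7)
  v <- rpois(100, 3)
  trk2 <- coverage_track(list(chr1 = v), library_size = sum(v))
  expect_equal(count_reads(trk2, peaks_from_bed("chr1", 30, 70))$count,
               sum(v[31:70]))
  parts <- peaks_from_bed("chr1", c(30, 45, 60), c(45, 60, 70))
  expect_equal(sum(count_reads(trk2, parts)$count),
               count_reads(trk2, peaks_from_bed("chr1", 30, 70))$count)
})

test_that("promoter windows are strand-aware and clip at chromosome start", {
  tp <- tx_from_bed("chr1", 10000, 15000, "+", chrom_len = 1e6)
  w <- promoter_window(tp)
  # 0-based [9800, 10500)
  expect_equal(c(start(w) - 1L, end(w)), c(9800L, 10500L))
  expect_equal(width(w), 700L)
  tm <- tx_from_bed("chr1", 5000, 10001, "-", chrom_len = 1e6)  # tss0 10000
  wm <- promoter_window(tm)
  # 0-based [9501, 10201)
  expect_equal(c(start(wm) - 1L, end(wm)), c(9501L, 10201L))
  expect_equal(width(wm), 700L)
  # clipped at the chromosome start: tss0 100 -> [0, 600)
  tc <- tx_from_bed("chr1", 100, 5000, "+", chrom_len = 1e6)
  wc <- promoter_window(tc)
  expect_equal(c(start(wc) - 1L, end(wc)), c(0L, 600L))
  expect_equal(width(wc), 600L)
})

test_that("body windows start +500 from the TSS and flag short transcripts", {
  tp <- tx_from_bed("chr1", 1000, 5000, "+", chrom_len = 1e6)
  b <- body_window(tp)
  expect_true(b$valid)
  expect_equal(start(b) - 1L, 1500L)
  expect_equal(end(b), 5000L)
  tm <- tx_from_bed("chr1", 1000, 5000, "-", chrom_len = 1e6)
  bm <- body_window(tm)
  expect_equal(c(start(bm) - 1L, end(bm)), c(1000L, 4500L))
  short <- tx_from_bed("chr1", 1000, 1400, "+", chrom_len = 1e6)
  expect_false(body_window(short)$valid)
})

test_that("bedGraph round-trip reproduces a coverage track", {
  set.seed(3)
  v <- rpois(200, 1)
  trk <- coverage_track(list(chr1 = v), factor = "Pol2", condition = "U")
  p <- tempfile(fileext = ".bedGraph")
  write_bedgraph(trk, p)
  back <- read_bedgraph(p, c(chr1 = 200L))
  expect_equal(as.numeric(back$cov$chr1), v)
  expect_equal(back$library_size, sum(v))
})
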