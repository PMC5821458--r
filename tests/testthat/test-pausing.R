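# Transcript collapsing, the pausing-index statistic, classification,
# eligibility filtering and gene-set crosstabs.

make_track <- function(values, lib = NULL) {
  coverage_track(list(chr1 = values), library_size = lib)
}

# A + strand transcript with TSS at 0-based position 400 so its promoter
# window [200, 900) covers track bases 201..900 and its body the next
# `body_len` bases.
one_tx <- function(body_len = 3000) {
  tx_from_bed("chr1", 400, 900 + body_len, "+", id = "t1", gene = "g1",
              chrom_len = 900 + body_len + 100)
}

test_that("transcripts sharing a 5' end collapse to the longest extent", {
  tx <- tx_from_bed("chr1", c(100, 100), c(5000, 3000), "+",
                    id = c("T1", "T2"), gene = c("g", "g"))
  cl <- collapse_transcripts(tx)
  expect_length(cl, 1)
  expect_equal(c(start(cl) - 1L, end(cl)), c(100L, 5000L))
  expect_equal(cl$transcript_id, "T1")
  expect_equal(cl$n_collapsed, 2L)
  # representative id is the lexicographically smallest member
  tx_ids <- tx_from_bed("chr1", c(100, 100), c(3000, 5000), "+",
                        id = c("B2", "A1"), gene = c("g", "g"))
  expect_equal(collapse_transcripts(tx_ids)$transcript_id, "A1")
})

test_that("distinct 5' ends and strands are never collapsed", {
  tx <- tx_from_bed("chr1", c(100, 101), c(5000, 5000), "+",
                    id = c("T1", "T3"), gene = c("g1", "g2"))
  expect_length(collapse_transcripts(tx), 2)
  tx2 <- tx_from_bed("chr1", c(100, 100), c(5000, 5000), c("+", "-"),
                     id = c("T1", "T4"), gene = c("g1", "g2"))
  expect_length(collapse_transcripts(tx2), 2)
})

test_that("collapsing is idempotent", {
  g <- generate_genome(synth_params(n_genes = 50, multi_tx_fraction = 0.6), 2)
  c1 <- collapse_transcripts(g$transcripts)
  c2 <- collapse_transcripts(c1)
  expect_identical(ranges(c1), ranges(c2))
  expect_identical(c1$transcript_id, c2$transcript_id)
  # every collapsed model spans its group's farthest 3' end
  expect_true(all(width(c1) >= 601))
})

test_that("the pausing index reproduces its closed form", {
  # densities 1 (promoter, 700/700) and 0.5 (body, 1500/3000) per million
  trk <- make_track(c(rep(0, 200), rep(1, 700), rep(0.5, 3000), rep(0, 100)),
                    lib = 1e6)
  res <- compute_pausing_index(trk, one_tx())
  expect_equal(res$pi, log(2) / log(1.5), tolerance = 1e-12)
  expect_equal(res$pi_class, "paused")
  expect_equal(res$promoter_count, 700)
  expect_equal(res$body_count, 1500)
})

test_that("degenerate windows hit the documented special cases", {
  # empty promoter, signal in body: PI = 0, non-paused
  trk0 <- make_track(c(rep(0, 900), rep(2, 3000), rep(0, 100)), lib = 1e6)
  r0 <- compute_pausing_index(trk0, one_tx())
  expect_equal(r0$pi, 0)
  expect_equal(r0$pi_class, "non_paused")
  # promoter signal, empty body: PI infinite, paused
  trk_inf <- make_track(c(rep(0, 200), rep(3, 700), rep(0, 3100)), lib = 1e6)
  r_inf <- compute_pausing_index(trk_inf, one_tx())
  expect_equal(r_inf$pi, Inf)
  expect_equal(r_inf$pi_class, "paused")
  # both empty: undefined
  r_na <- compute_pausing_index(make_track(rep(0, 3800), lib = 1e6), one_tx())
  expect_true(is.na(r_na$pi))
  expect_equal(r_na$pi_class, "undefined")
  # equal densities: PI exactly 1, ambiguous (thresholds are strict)
  tr_eq <- make_track(c(rep(0, 200), rep(1, 3700)), lib = 1e6)
  r_eq <- compute_pausing_index(tr_eq, one_tx())
  expect_equal(r_eq$pi, 1)
  expect_equal(r_eq$pi_class, "ambiguous")
  # a transcript too short for a body is flagged, not an error
  short <- tx_from_bed("chr1", 200, 600, "+", id = "s", gene = "s",
                       chrom_len = 3800)
  expect_false(compute_pausing_index(make_track(rep(1, 3800)), short)$eligible)
})

test_that("classification thresholds follow the PI rule", {
  expect_equal(classify_pi(c(1.7, 0.5, 0.9, 1.0, 0.8, NA, Inf)),
               c("paused", "non_paused", "ambiguous", "ambiguous",
                 "ambiguous", "undefined", "paused"))
})

test_that("classification is invariant to the log base", {
  set.seed(31)
  d <- matrix(rexp(2000 * 2, rate = 0.5), ncol = 2)
  pi2 <- log2(1 + d[, 1]) / log2(1 + d[, 2])
  pie <- log(1 + d[, 1]) / log(1 + d[, 2])
  expect_identical(classify_pi(pi2), classify_pi(pie))
  # and PI > 1 exactly when the promoter density exceeds the body density
  expect_identical(pi2 > 1, d[, 1] > d[, 2])
})

test_that("PI is monotone in promoter and body signal", {
  lib <- 1e6
  base_body <- rep(0.5, 3000)
  pis_up <- sapply(c(100, 400, 700, 1400), function(k) {
    trk <- make_track(c(rep(0, 200), rep(k / 700, 700), base_body,
                        rep(0, 100)), lib = lib)
    compute_pausing_index(trk, one_tx())$pi
  })
  expect_true(all(diff(pis_up) > 0))
  pis_down <- sapply(c(300, 900, 1800, 3000), function(k) {
    trk <- make_track(c(rep(0, 200), rep(1, 700), rep(k / 3000, 3000),
                        rep(0, 100)), lib = lib)
    compute_pausing_index(trk, one_tx())$pi
  })
  expect_true(all(diff(pis_down) < 0))
})

test_that("promoter-peak eligibility matches an all-pairs oracle", {
  # worked example: window [9800,10500) with a peak [10400,10600)
  tx <- tx_from_bed("chr1", 10000, 15000, "+", chrom_len = 2e4)
  trk <- make_track(rep(1, 2e4))
  res <- compute_pausing_index(trk, tx)
  expect_true(filter_by_promoter_peaks(
    res, peaks_from_bed("chr1", 10400, 10600))$eligible)
  expect_false(filter_by_promoter_peaks(
    res, peaks_from_bed("chr1", 11000, 11200))$eligible)

  set.seed(32)
  n <- 100
  starts <- sample.int(5e4, n)
  txs <- tx_from_bed("chr1", starts, starts + 2000,
                     sample(c("+", "-"), n, TRUE),
                     id = paste0("t", 1:n), gene = paste0("g", 1:n),
                     chrom_len = 6e4)
  peaks <- random_intervals(60, max_pos = 55000L, max_len = 400L)
  big <- make_track(rep(1, 6e4))
  resn <- compute_pausing_index(big, txs)
  flagged <- filter_by_promoter_peaks(resn, peaks)
  prom <- GRanges(resn$chrom, IRanges(resn$promoter_start,
                                      resn$promoter_end))
  expect_identical(flagged$eligible, brute_overlaps_any(prom, peaks))
})

test_that("crosstabs count classes among eligible set members", {
  res <- data.frame(
    transcript_id = paste0("t", 1:4), gene_id = paste0("g", 1:4),
    chrom = "chr1", strand = "+",
    promoter_start = 1, promoter_end = 700,
    body_start = 701, body_end = 3000,
    promoter_count = 0, body_count = 0,
    promoter_density = 0, body_density = 0,
    pi = c(1.5, 0.5, 0.9, 2.0),
    pi_class = c("paused", "non_paused", "ambiguous", "paused"),
    eligible = c(TRUE, TRUE, TRUE, FALSE))
  ct <- crosstab_pi(paste0("g", 1:3), res)
  expect_equal(unname(ct$counts[c("paused", "non_paused", "ambiguous")]),
               c(1L, 1L, 1L))
  # the ineligible paused transcript g4 is not counted
  expect_equal(ct$n_eligible, 3L)
  # the PI > 0.8 margin counts paused plus ambiguous-above-threshold
  expect_equal(ct$n_pi_above_nonpaused, 2L)
  # empty set: zero counts, NA fractions
  ct0 <- crosstab_pi(character(), res)
  expect_equal(sum(ct0$counts), 0L)
  expect_true(all(is.na(ct0$fractions)))
})

test_that("noiseless synthetic coverage is classified perfectly", {
  g <- generate_genome(synth_params(n_genes = 80, noise = FALSE), 13)
  trk <- generate_coverage(g, "U", "Pol2", 13)
  res <- compute_pausing_index(trk, collapse_transcripts(g$transcripts))
  truth <- g$truth$pausing_class[match(res$gene_id, g$truth$gene_id)]
  keep <- truth %in% c("paused", "non_paused")
  expect_equal(mean(res$pi_class[keep] == truth[keep]), 1)
})
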