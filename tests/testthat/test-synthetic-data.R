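# Generator contracts: determinism, class-fraction calibration, the
# coverage and peak structure the pipeline is meant to detect, and
# round-trips through the on-disk formats.

test_that("the generator is deterministic in (seed, params) and seed-sensitive", {
  p <- synth_params(n_genes = 40)
  g1 <- generate_genome(p, 11)
  g2 <- generate_genome(p, 11)
  expect_identical(g1$truth, g2$truth)
  expect_identical(ranges(g1$transcripts), ranges(g2$transcripts))
  g3 <- generate_genome(p, 12)
  expect_false(identical(g1$truth, g3$truth))

  c1 <- generate_coverage(g1, "U", "Pol2", 11)
  c2 <- generate_coverage(g1, "U", "Pol2", 11)
  expect_identical(c1$cov, c2$cov)
  k1 <- generate_peaks(g1, "GR", "LD", 1, 11)
  k2 <- generate_peaks(g1, "GR", "LD", 1, 11)
  expect_identical(ranges(k1), ranges(k2))
  m1 <- generate_counts(g1, synth_design(reps = 2), 11)
  m2 <- generate_counts(g1, synth_design(reps = 2), 11)
  expect_identical(m1$counts, m2$counts)
})

test_that("zero genes yield an empty annotation and truth", {
  g <- generate_genome(synth_params(n_genes = 0), 1)
  expect_length(g$transcripts, 0)
  expect_equal(nrow(g$truth), 0)
})

test_that("realized class counts sit in the exact binomial 99% interval", {
  p <- synth_params(n_genes = 200)
  g <- generate_genome(p, 1)
  n_paused <- sum(g$truth$pausing_class == "paused")
  lo <- qbinom(0.005, 200, p$fraction_paused)
  hi <- qbinom(0.995, 200, p$fraction_paused)
  expect_gte(n_paused, lo)
  expect_lte(n_paused, hi)
  n_np <- sum(g$truth$pausing_class == "non_paused")
  expect_gte(n_np, qbinom(0.005, 200, p$fraction_nonpaused))
  expect_lte(n_np, qbinom(0.995, 200, p$fraction_nonpaused))
})

test_that("noiseless Pol2 coverage has the designed promoter/body structure", {
  p <- synth_params(n_genes = 40, noise = FALSE)
  g <- generate_genome(p, 3)
  trk <- generate_coverage(g, "U", "Pol2", 3)
  ctx <- collapse_transcripts(g$transcripts)
  res <- compute_pausing_index(trk, ctx,
                               pausing_params(density_scale = FALSE))
  cls <- g$truth$pausing_class[match(res$gene_id, g$truth$gene_id)]
  # paused genes: promoter density at least the design ratio over body
  pg <- cls == "paused"
  expect_true(all(res$promoter_density[pg] / res$body_density[pg] >=
                    p$promoter_to_body_ratio - 0.2))
  # non-paused genes untreated carry only the basal body level: their
  # total signal is bounded by that level times the window, far below
  # their own LPS level
  ng <- which(cls == "non_paused")
  trk_l <- generate_coverage(g, "L", "Pol2", 3)
  res_l <- compute_pausing_index(trk_l, ctx,
                                 pausing_params(density_scale = FALSE))
  tot_u <- res$promoter_count[ng] + res$body_count[ng]
  span <- (res$promoter_end - res$promoter_start + 1) +
    (res$body_end - res$body_start + 1)
  expect_true(all(tot_u <= p$nonpaused_density_u * span[ng] + 1e-9))
  # only induced genes load Pol2 under LPS
  ind <- g$truth$sensitivity[match(res$gene_id, g$truth$gene_id)] !=
    "not_induced"
  ngi <- which(cls == "non_paused" & ind)
  tot_li <- res_l$promoter_count[ngi] + res_l$body_count[ngi]
  tot_ui <- res$promoter_count[ngi] + res$body_count[ngi]
  expect_true(all(tot_li > p$lps_body_gain * 0.8 * tot_ui))
})

test_that("paused genes keep a high pausing index under LPS+Dex", {
  g <- generate_genome(synth_params(n_genes = 200), 1)
  trk <- generate_coverage(g, "LD", "Pol2", 1)
  ctx <- collapse_transcripts(g$transcripts)
  res <- compute_pausing_index(trk, ctx)
  pg <- res$gene_id %in% g$truth$gene_id[g$truth$pausing_class == "paused"]
  expect_gte(mean(res$pi[pg] > 1, na.rm = TRUE), 0.95)
})

test_that("replicate 2 equals replicate 1 when drop-out and jitter are off", {
  p <- synth_params(n_genes = 30, replicate_dropout = 0,
                    replicate_jitter_sd = 0)
  g <- generate_genome(p, 5)
  r1 <- generate_peaks(g, "p65", "L", 1, 5)
  r2 <- generate_peaks(g, "p65", "L", 2, 5)
  expect_identical(ranges(r1), ranges(r2))
})

test_that("Dex-repressed genes gain GR peaks on their p65 sites only under LPS+Dex", {
  g <- generate_genome(synth_params(n_genes = 60), 2)
  ctx <- collapse_transcripts(g$transcripts)
  gr_ld <- generate_peaks(g, "GR", "LD", 1, 2)
  gr_d <- generate_peaks(g, "GR", "D", 1, 2)
  p65_ld <- generate_peaks(g, "p65", "LD", 1, 2)
  rep_ids <- g$truth$gene_id[g$truth$sensitivity == "dex_repressed"]
  rep_tx <- ctx[ctx$gene_id %in% rep_ids]
  assoc <- gene_window_association(gr_ld, rep_tx, flank = 100000L)
  # every repressed gene has >= 1 GR peak in its window overlapping p65
  for (gid in rep_ids) {
    idx <- assoc$peak_index[assoc$gene_id == gid]
    expect_true(any(overlapsAny(gr_ld[idx], p65_ld, ignore.strand = TRUE)))
  }
  # Dex-alone GR binding is GRE background: far fewer peaks than LPS+Dex
  expect_lt(length(gr_d), length(gr_ld))
  expect_equal(length(gr_d), g$params$n_background_gre)
})

test_that("NELF promoter occupancy is calibrated to the class probabilities", {
  p <- synth_params(n_genes = 300)
  g <- generate_genome(p, 1)
  pk <- generate_peaks(g, "NELF", "U", 1, 1)
  ctx <- collapse_transcripts(g$transcripts)
  prom <- promoter_window(ctx)
  occ <- overlapsAny(prom, pk, ignore.strand = TRUE)
  gene_occ <- tapply(occ, ctx$gene_id, any)
  for (cl in c("paused", "non_paused")) {
    ids <- g$truth$gene_id[g$truth$pausing_class == cl]
    k <- sum(gene_occ[ids])
    n <- length(ids)
    pr <- if (cl == "paused") p$nelf_prob_paused[["U"]]
    else p$nelf_prob_nonpaused[["U"]]
    expect_gte(k, qbinom(0.005, n, pr))
    expect_lte(k, qbinom(0.995, n, pr))
    # and the peaks match the truth draw exactly (detection is by design
    # loss-free)
    expect_equal(unname(k), sum(g$truth$nelf_U[g$truth$gene_id %in% ids]))
  }
})

test_that("count matrix folds follow the truth labels", {
  p <- synth_params(n_genes = 150, nb_dispersion = 0)
  g <- generate_genome(p, 4)
  cm <- generate_counts(g, synth_design(reps = 3), 4)
  cond <- cm$design$condition
  mU <- rowMeans(cm$counts[, cond == "U"])
  mL <- rowMeans(cm$counts[, cond == "L"])
  mLD <- rowMeans(cm$counts[, cond == "LD"])
  ni <- g$truth$sensitivity == "not_induced"
  # dispersion 0 (Poisson): uninduced fold concentrates at 1
  expect_lt(median(abs(log2(mL[ni] / mU[ni]))), 0.2)
  ind <- !ni
  expect_gt(min(mL[ind] / mU[ind]), p$induction_fold * 0.8)
  repg <- g$truth$sensitivity == "dex_repressed"
  expect_gt(min(mL[repg] / mLD[repg]), p$attenuation_fold * 0.9)
  ins <- g$truth$sensitivity == "dex_insensitive"
  expect_lt(median(abs(log2(mL[ins] / mLD[ins]))), 0.2)
})

test_that("NELF-complex knockout lifts Dex attenuation at paused genes only", {
  p <- synth_params(n_genes = 200, nb_dispersion = 0)
  g <- generate_genome(p, 6)
  ko <- generate_counts(g, synth_design(reps = 2, genotype = "KO"), 6)
  cond <- ko$design$condition
  mL <- rowMeans(ko$counts[, cond == "L"])
  mLD <- rowMeans(ko$counts[, cond == "LD"])
  repg <- g$truth$sensitivity == "dex_repressed"
  paused <- g$truth$pausing_class == "paused"
  if (any(repg & paused)) {
    expect_lt(median(abs(log2(mL / mLD)[repg & paused])), 0.2)
  }
  if (any(repg & !paused)) {
    expect_gt(min((mL / mLD)[repg & !paused]), p$attenuation_fold * 0.9)
  }
})

test_that("written artifacts round-trip through the standard formats", {
  g <- generate_genome(synth_params(n_genes = 25), 8)
  dir <- tempfile()
  write_synth_genome(g, dir)
  sizes <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  expect_identical(sizes, g$chrom_sizes)
  tx <- read_transcripts(file.path(dir, "annotation.gtf"), sizes)
  expect_identical(ranges(tx), ranges(g$transcripts))
  expect_identical(tx$transcript_id, g$transcripts$transcript_id)

  pk <- generate_peaks(g, "NELF", "U", 1, 8)
  np <- file.path(dir, "nelf.narrowPeak")
  write_peaks(pk, np)
  pk2 <- read_peaks(np)
  expect_identical(ranges(pk), ranges(pk2))
  expect_identical(pk$summit, pk2$summit)

  trk <- generate_coverage(g, "U", "NELF", 8)
  bg <- file.path(dir, "nelf.bedGraph")
  write_bedgraph(trk, bg)
  trk2 <- read_bedgraph(bg, g$chrom_sizes)
  expect_identical(lapply(trk$cov, as.numeric), lapply(trk2$cov, as.numeric))
})
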