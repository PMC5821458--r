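# Differential gene-set derivation: weighted trimmed-mean (TMM) scale
# normalization, log-CPM, a common-dispersion negative-binomial exact test,
# and the induction/attenuation threshold logic that defines the
# LPS-induced, Dex-repressed and Dex-insensitive sets.
#
# TMM and the exact test are implemented here from their published
# definitions so the pipeline's gene-set contract is self-contained and can
# be checked against a reference implementation in the test suite.

#' Weighted trimmed mean of M-values (TMM) scale factors
#'
#' Between-sample normalization factors computed by the weighted trimmed
#' mean of M-values: per-gene log2 ratios (M) against a reference sample are
#' trimmed by `trim_m` on each tail, average log2 abundances (A) by
#' `trim_a`, and the surviving M-values averaged with inverse
#' delta-method-variance weights. Factors are rescaled so their geometric
#' mean is 1. The automatic reference is the sample whose 75th count
#' percentile (counts divided by library size) is closest to the mean across
#' samples.
#'
#' @param counts Integer matrix, genes x samples.
#' @param lib_size Library sizes; default column sums.
#' @param trim_m Two-sided trim fraction on log-ratios (default 0.30).
#' @param trim_a Two-sided trim fraction on average abundance (default 0.05).
#' @param reference Column index or name of the reference sample, or `NULL`
#'   for automatic selection.
#' @return Numeric vector of per-sample scale factors.
#' @export
tmm_factors <- function(counts, lib_size = colSums(counts),
                        trim_m = 0.30, trim_a = 0.05, reference = NULL) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 2, all(lib_size > 0))
  if (is.null(reference)) {
    q75 <- vapply(seq_len(ncol(counts)), function(j)
      quantile(counts[, j] / lib_size[j], 0.75, names = FALSE), numeric(1))
    reference <- which.min(abs(q75 - mean(q75)))
  } else if (is.character(reference)) {
    reference <- match(reference, colnames(counts))
  }
  ref <- counts[, reference]
  nR <- lib_size[reference]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]
    nO <- lib_size[j]
    logR <- log2((obs / nO) / (ref / nR))
    absE <- (log2(obs / nO) + log2(ref / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
    fin <- is.finite(logR) & is.finite(absE)
    if (!any(fin)) {
      stop("sample ", j, " shares no co-expressed genes with the reference")
    }
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(logR) >= loM & rank(logR) <= hiM &
      rank(absE) >= loA & rank(absE) <= hiA
    m <- sum(logR[keep] / v[keep], na.rm = TRUE) /
      sum(1 / v[keep], na.rm = TRUE)
    if (is.na(m)) m <- 0
    2^m
  }, numeric(1))
  f / exp(mean(log(f)))
}

#' Log2 counts per million on TMM-effective library sizes
#'
#' `log2((count + prior) / (lib_size * factor + 2 * prior) * 1e6)`, the
#' standard prior-damped log-CPM: the pseudo-count keeps zeros finite and
#' the doubled prior in the denominator keeps the transform scale-invariant
#' in the zero-prior limit.
#'
#' @param counts Integer matrix, genes x samples.
#' @param factors TMM factors from [tmm_factors()] (default all 1).
#' @param lib_size Library sizes; default column sums.
#' @param prior Pseudo-count (default 0.5).
#' @return Matrix of log2-CPM values.
#' @export
log_cpm <- function(counts, factors = rep(1, ncol(counts)),
                    lib_size = colSums(counts), prior = 0.5) {
  counts <- as.matrix(counts)
  if (any(lib_size <= 0)) stop("zero or negative library size")
  eff <- lib_size * factors
  t(log2(t(counts + prior) / (eff + 2 * prior) * 1e6))
}

# Conditional negative-binomial log-likelihood of a dispersion value, given
# each gene's within-group total, summed over genes and groups. Assumes
# (approximately) equal library sizes within the matrix, i.e. counts have
# been scaled to a common effective library.
cond_loglik <- function(counts, group, phi) {
  r <- 1 / phi
  ll <- 0
  for (g in unique(group)) {
    y <- counts[, group == g, drop = FALSE]
    n <- ncol(y)
    z <- rowSums(y)
    ll <- ll + sum(lgamma(y + r)) - nrow(y) * n * lgamma(r) -
      sum(lgamma(z + n * r)) + nrow(y) * lgamma(n * r)
  }
  ll
}

# Maximum conditional-likelihood common dispersion on a log-spaced grid.
estimate_common_dispersion <- function(counts, group,
                                       grid = exp(seq(log(1e-4), log(2),
                                                      length.out = 81))) {
  ll <- vapply(grid, function(phi) cond_loglik(counts, group, phi),
               numeric(1))
  grid[which.max(ll)]
}

# Exact two-sided p-value for a difference between two groups of NB counts
# with common dispersion phi and equal library sizes, conditioning on the
# combined total. The conditional law of the group-A total is negative
# hypergeometric, free of the mean; in the phi -> 0 limit it reduces to the
# binomial exact test. The two-sided p-value sums all outcomes no more
# probable than the observed one.
nb_exact_pvalue <- function(zA, zB, nA, nB, phi) {
  z <- zA + zB
  if (z == 0) return(1)
  k <- 0:z
  if (phi <= 1e-8) {
    logp <- stats::dbinom(k, z, nA / (nA + nB), log = TRUE)
  } else {
    r <- 1 / phi
    logp <- lgamma(k + nA * r) - lgamma(k + 1) - lgamma(nA * r) +
      lgamma(z - k + nB * r) - lgamma(z - k + 1) - lgamma(nB * r)
    logp <- logp - max(logp)
    logp <- logp - log(sum(exp(logp)))
  }
  pk <- exp(logp)
  min(1, sum(pk[pk <= pk[zA + 1] * (1 + 1e-12)]))
}

#' Common-dispersion negative-binomial exact test between two conditions
#'
#' Counts are first scaled to a common effective library (TMM factor times
#' library size, rescaled to the geometric mean and rounded), the common
#' dispersion is estimated by maximizing the conditional likelihood given
#' each gene's within-group total on a grid, and each gene's two-sided
#' p-value comes from the exact conditional distribution of the group total.
#' Log2 fold changes are differences of prior-damped group-mean log-CPM.
#'
#' @param counts Integer matrix, genes x samples.
#' @param condition Per-sample condition labels.
#' @param contrast Length-2 character: `c(numerator, denominator)`; the
#'   reported logFC is `log2(numerator / denominator)`.
#' @param factors TMM factors; computed if `NULL`.
#' @param dispersion Common NB dispersion; estimated if `NULL`.
#' @param prior Pseudo-count for the logFC (default 0.5).
#' @return A `data.frame` with `gene_id`, `logFC`, `pvalue`, `fdr`
#'   (Benjamini-Hochberg) and the per-group mean log-CPM.
#' @export
de_test <- function(counts, condition, contrast, factors = NULL,
                    dispersion = NULL, prior = 0.5) {
  counts <- as.matrix(counts)
  stopifnot(length(condition) == ncol(counts), length(contrast) == 2)
  if (!all(contrast %in% condition)) {
    stop("contrast condition absent from the design: ",
         paste(setdiff(contrast, condition), collapse = ", "))
  }
  sel <- condition %in% contrast
  y <- counts[, sel, drop = FALSE]
  grp <- condition[sel]
  if (any(table(grp) < 2)) stop("need at least 2 replicates per condition")
  lib <- colSums(y)
  if (is.null(factors)) factors <- tmm_factors(y, lib)
  eff <- lib * factors
  common <- exp(mean(log(eff)))
  # scale to a common library so the conditional test's equal-size
  # assumption holds; rounding keeps counts integral
  ps <- round(t(t(y) * (common / eff)))
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(ps, grp)
  }
  nA <- sum(grp == contrast[1])
  nB <- sum(grp == contrast[2])
  zA <- rowSums(ps[, grp == contrast[1], drop = FALSE])
  zB <- rowSums(ps[, grp == contrast[2], drop = FALSE])
  pvalue <- vapply(seq_len(nrow(ps)), function(i)
    nb_exact_pvalue(zA[i], zB[i], nA, nB, dispersion), numeric(1))
  lc <- log_cpm(y, factors, lib, prior = prior)
  meanA <- rowMeans(lc[, grp == contrast[1], drop = FALSE])
  meanB <- rowMeans(lc[, grp == contrast[2], drop = FALSE])
  ids <- rownames(counts)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(counts)))
  out <- data.frame(gene_id = ids, logFC = meanA - meanB,
                    pvalue = pvalue, fdr = p.adjust(pvalue, "BH"),
                    mean_log_cpm_a = meanA, mean_log_cpm_b = meanB,
                    stringsAsFactors = FALSE)
  attr(out, "dispersion") <- dispersion
  attr(out, "contrast") <- contrast
  out
}

#' Derive LPS-induced, Dex-repressed and Dex-insensitive gene sets
#'
#' A gene is LPS-induced when its L-vs-U fold change exceeds `induce_fold`
#' and it passes the significance gate; an induced gene is Dex-repressed
#' when its L-vs-LD fold change exceeds `attenuate_fold` (a pure fold
#' filter, no second significance gate), and Dex-insensitive otherwise.
#' Folds are computed on the prior-damped log-CPM scale carried by the test
#' results. The significance gate is FDR-based by default; `sig_mode =
#' "raw_p"` gates on the unadjusted p-value instead (both gates appear in
#' practice and the choice is deliberately exposed).
#'
#' @param de_l_vs_u [de_test()] result for L vs U.
#' @param de_l_vs_ld [de_test()] result for L vs LD on the same genes.
#' @param induce_fold Induction threshold (default 1.5).
#' @param attenuate_fold Attenuation threshold (default 1.3).
#' @param sig_threshold Significance threshold (default 0.1).
#' @param sig_mode `"fdr"` (default) or `"raw_p"`.
#' @return A list of three character vectors: `lps_induced`,
#'   `dex_repressed`, `dex_insensitive`. Always
#'   `dex_repressed ∪ dex_insensitive = lps_induced`, disjointly.
#' @export
derive_gene_sets <- function(de_l_vs_u, de_l_vs_ld, induce_fold = 1.5,
                             attenuate_fold = 1.3, sig_threshold = 0.1,
                             sig_mode = c("fdr", "raw_p")) {
  sig_mode <- match.arg(sig_mode)
  if (nrow(de_l_vs_u) == 0) stop("empty gene universe")
  if (!setequal(de_l_vs_u$gene_id, de_l_vs_ld$gene_id)) {
    stop("the two contrasts cover different gene universes")
  }
  de_l_vs_ld <- de_l_vs_ld[match(de_l_vs_u$gene_id, de_l_vs_ld$gene_id), ]
  sig <- if (sig_mode == "fdr") de_l_vs_u$fdr < sig_threshold
  else de_l_vs_u$pvalue < sig_threshold
  induced <- sig & de_l_vs_u$logFC > log2(induce_fold)
  attenuated <- de_l_vs_ld$logFC > log2(attenuate_fold)
  list(lps_induced = de_l_vs_u$gene_id[induced],
       dex_repressed = de_l_vs_u$gene_id[induced & attenuated],
       dex_insensitive = de_l_vs_u$gene_id[induced & !attenuated])
}

#' Tally genes passing fold-repression filters in a second dataset
#'
#' Applies cumulative fold-repression cutoffs (e.g. >= 1.3-fold and
#' >= 2-fold repression under Dex alone) to a fold-change vector restricted
#' to a gene set, as used to ask how many LPS-context Dex-repressed genes
#' are also repressed by Dex without LPS.
#'
#' @param logfc Named numeric vector of log2 fold changes
#'   (reference / treated, so repression is positive).
#' @param gene_set Character vector of gene ids to restrict to.
#' @param folds Fold cutoffs (default `c(1.3, 2)`).
#' @return Named integer vector of tallies, one per cutoff.
#' @export
repression_filter_tally <- function(logfc, gene_set, folds = c(1.3, 2)) {
  x <- logfc[names(logfc) %in% gene_set]
  vapply(folds, function(f) sum(x >= log2(f), na.rm = TRUE), integer(1)) |>
    setNames(paste0("fold_", folds))
}
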