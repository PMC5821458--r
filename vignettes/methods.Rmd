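---
title: "Methods: pausing classification and cistrome co-occupancy in grpause"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pausing classification and cistrome co-occupancy in grpause}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grpause)
```

## Scope and model

`grpause` analyses acute glucocorticoid repression of LPS-induced genes in
three coupled layers:

1. **Expression layer.** An RNA-seq count matrix over conditions U
   (untreated), L (LPS) and LD (LPS + dexamethasone) yields three gene
   sets: LPS-induced (fold > 1.5 at FDR < 0.1), Dex-repressed (induced and
   attenuated > 1.3-fold by Dex) and Dex-insensitive (the remainder of the
   induced set). By construction the repressed and insensitive sets
   partition the induced set — a conservation law the tests assert on every
   input.
2. **Pausing layer.** Untreated Pol II ChIP coverage is summarized per
   transcript by the pausing index, the ratio of log-transformed,
   length- and library-normalized read densities in a promoter window
   (−200/+500 nt around the TSS) and the gene body (+500 to the 3' end).
   PI > 1 is paused, PI < 0.8 non-paused, the band between ambiguous.
3. **Cistrome layer.** Peak sets per factor/condition/replicate are merged
   (union of replicates), partitioned by mutual overlap (≥ 1 nt), annotated
   to genomic features, associated with genes through ±100-kb windows, and
   summarized as class-conditional promoter-occupancy fractions with exact
   binomial intervals, plus TSS-anchored metagene matrices and profiles.

## Statistical choices

**TMM and log-CPM.** Scale factors follow the published weighted
trimmed-mean-of-M-values algorithm exactly (30% two-sided trim on
log-ratios, 5% on average abundance, delta-method inverse-variance weights,
geometric-mean normalization, automatic reference by the 75th-percentile
rule). The implementation is self-contained; the test suite checks it to
1e-10 against an independent reference implementation. Expression is
`log2((count + 0.5) / (effective library + 1) * 1e6)`; the doubled prior in
the denominator makes the transform scale-invariant in the zero-prior
limit and keeps zero counts finite.

**Exact test.** Differential calls use a common-dispersion
negative-binomial exact test. Counts are scaled (and rounded) to a common
effective library so groups are exchangeable; the common dispersion
maximizes the conditional likelihood given each gene's within-group total
on an 81-point log-spaced grid over [1e-4, 2]; the two-sided p-value sums
all outcomes of the conditional law of the group total that are no more
probable than the one observed. That law is negative hypergeometric —
free of the unknown mean — and converges to the binomial law as dispersion
vanishes, which the tests assert. Tagwise dispersion, GLMs and covariates
are deliberately out of scope: the contract is the gene-set logic, not a
general DE framework. Under a 2000-gene null simulation the empirical
type-I error at α = 0.05 is ~0.045–0.05.

**Two significance conventions.** The induced set can be gated on FDR
(default, threshold 0.1) or on the raw p-value (`sig_mode = "raw_p"`);
both gates are used in practice for this kind of derivation and the choice
is exposed rather than resolved. Attenuation (> 1.3-fold) is a pure fold
filter with no second significance gate; its fold is computed on
prior-damped log-CPM group means, which prevents infinite folds at zero
counts at the cost of slightly shrinking large folds.

**Pausing index.** The statistic is read literally as a ratio of logs,
`log(1 + d_p) / log(1 + d_b)`, not a log of a ratio. The +1 pseudocount
(configurable) makes the statistic finite and sign-stable at low
densities; because the same base appears in numerator and denominator the
classification is invariant to the base, which is asserted on 10⁴ random
density pairs. Library normalization is applied to the densities *before*
the logs — per-million scaling of a ratio of logs after the fact has no
coherent unit. Special cases: zero body with nonzero promoter is +Inf
(paused); both windows empty is undefined; equal densities give exactly 1
(ambiguous — the thresholds are strict inequalities, so boundary
transcripts belong to neither class). Bodies shorter than 100 nt after the
+500 offset make a transcript ineligible: a density over a tiny window is
unstable. Transcripts sharing a 5' end are collapsed to one model spanning
to the farthest 3' end (representative: lexicographically smallest id);
the operation is idempotent. Classification uses untreated coverage while
peak eligibility uses LPS-condition Pol II peaks — an intentional
asymmetry, since pausing is defined in the resting state but only
transcripts with detectable Pol II under stimulation are scoreable.

**Occupancy and overlap.** All peak–peak and peak–window overlap is
unstranded with a 1-nt minimum, the standard cistrome convention. Venn
shared counts are asymmetric (A-peaks-overlapping-B versus the converse)
and both sides are reported; conservation holds per side. The promoter
window for occupancy calls defaults to the PI promoter window (−200/+500)
so "promoter-associated" means the same thing in both layers; feature
annotation uses a wider −2000/+500 promoter, matching common annotation
practice, and assigns exactly one category per peak from its summit
(midpoint fallback) with precedence promoter > exon > intron > downstream
> distal. Gene association uses the gene span plus a 100-kb flank on each
side (configurable) rather than a fixed 200-kb window centered on the
gene, so long genes are fully covered.

**Metagene.** Rows are transcript-oriented (minus-strand rows reversed) so
pause peaks align at the same x regardless of strand; the default window
is −200..+1500 at 10-nt bins (bin width is a display choice, exposed).
Confidence bands use the t quantile, not 1.96, so the band is coherent at
small n; n = 1 yields NA bands rather than a false zero. The shared
heat-map display cap is an order statistic (inverse-CDF quantile, default
99th percentile) of the pooled nonzero values; data are never truncated,
only the rendering saturates.

## The synthetic generator

The generator emulates the statistical structure the pipeline assumes, not
raw sequencing: coverage is emitted directly as per-base counts (no reads,
no sequence), peaks as intervals, expression as negative-binomial counts.
Its defaults are the experimental conditions the analysis targets:

- pause site 50 nt downstream of the TSS; the promoter bump is a
  discretized Gaussian (sd = width/4) — the minimal two-parameter shape
  consistent with qualitative track profiles;
- class fractions 24% paused / 66% non-paused, the remaining 10% built
  with promoter density equal to body density (PI ≈ 1, the ambiguous
  band);
- NELF promoter occupancy is Bernoulli per gene and condition — 0.863
  (paused) vs 0.317 (non-paused) untreated, 0.836/0.332 under LPS+Dex;
  the 1-h eviction (0.15/0.10) and 3-h reload (0.80/0.30) probabilities
  are free parameters, since no kinetic model is fitted;
- induction folds are drawn above the 1.5 threshold (log2 fold uniform on
  [log2 1.8, 3]) and attenuation folds above 1.3 (uniform on
  [log2 1.6, 2]), so designed effects always exceed the gates and recovery
  failures measure pipeline noise, not label ambiguity;
- GR binds background GRE-like loci whenever Dex is present and joins p65
  at the NF-kB sites of Dex-repressed genes only under LPS+Dex
  (tethering); p65 binding is LPS-dependent and Dex-resistant; an optional
  knockout genotype removes Dex attenuation specifically at paused
  repressed genes.

One design constraint deserves emphasis: the fraction of LPS-induced genes
defaults to 0.25, deliberately below the TMM log-ratio trim fraction
(0.30). With more one-sided differential genes than the trim removes, the
trimmed mean necessarily retains induced genes and biases every fold
change; real transcriptomes sit far below this (hundreds of induced genes
among more than ten thousand expressed), but a 300-gene desk-scale
simulation must respect the bound explicitly. Gene placement keeps genes
~200 kb apart (twice the association flank), lengths are uniform on
2–6 kb (min > 600 nt so bodies are non-empty), and ~30% of genes carry 2–3
transcripts sharing a 5' end to exercise collapsing.

Every artifact draws from its own RNG stream derived from (seed, artifact
name) via a polynomial string hash folded into the seed below 2³¹, so
adding artifacts never perturbs existing ones and one seed reproduces the
whole run byte-identically — the determinism the pipeline report asserts.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: mappability and GC artifacts, fragment-length
effects, peak-caller behavior (peaks are constructed, so occupancy
detection is loss-free), overdispersed coverage beyond Poisson, correlated
replicates, and annotation errors beyond shared-TSS redundancy. Recovery
rates on synthetic data are therefore upper bounds for real data.

## Problem sizes and degenerate inputs

Default validation runs use 300 genes, 3 RNA-seq replicates per condition,
two peak replicates per factor/condition, and a 2000-gene null for test
calibration; an end-to-end run completes in seconds. Windows running off
chromosome ends are clipped, never rejected, and densities use the clipped
length; regions on unknown chromosomes are an error. Empty gene classes
yield NA fractions with a warning; empty peak replicates union to the
other replicate; a genome of zero genes is a valid (empty) annotation.

## Limitations

The exact test assumes a common dispersion; strongly gene-specific
dispersion inflates false positives at the fold thresholds. The
attenuation gate is a pure fold filter, so its precision degrades with few
replicates (noise across the 1.3-fold boundary) — matching the derivation
it implements rather than improving on it. Feature annotation without exon
structure cannot distinguish exon from intron and says so. No motif
analysis, peak calling, or alignment is performed; peaks and coverage are
inputs.
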