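# grpause

Genome-wide classification of glucocorticoid-repressed inflammatory genes
by RNA polymerase II promoter-proximal pausing, with quantification of
transcription-factor co-occupancy around them.

## The problem

Macrophages challenged with LPS induce hundreds of pro-inflammatory genes;
co-treatment with a glucocorticoid (dexamethasone, Dex) rapidly represses a
large subset of them. Two activation modes coexist: *paused* genes hold
transcriptionally engaged Pol II ~50 nt downstream of the TSS (stabilized
by the negative elongation factor, NELF) and are induced by pause release,
while *non-paused* genes are induced by de novo Pol II recruitment.
Dissecting which mode a repressed gene uses — and how factor occupancy
(GR tethering to NF-kB p65, NELF promoter retention) differs between the
classes — requires a reproducible chain of genomic computations. `grpause`
implements that chain for anyone with gene models, coverage tracks, peak
calls and an RNA-seq count matrix, and ships a seeded synthetic-data
generator so every stage can be validated against known ground truth.

## The statistics at the core

**Gene sets.** Counts are TMM-normalized (weighted trimmed mean of
M-values; trim 30% on log-ratios, 5% on abundance, inverse-variance
weights) and expressed as prior-damped log2-CPM. Differential calls use a
common-dispersion negative-binomial exact test: with equalized effective
libraries the within-group total is conditioned on the gene's grand total,
whose law is negative hypergeometric and reduces to the binomial exact test
as dispersion vanishes. The derived sets are

- `lps_induced` = { FC(L/U) > 1.5 and FDR < 0.1 },
- `dex_repressed` = induced ∩ { FC(L/LD) > 1.3 },
- `dex_insensitive` = the rest of the induced set,

where U, L, LD are untreated, LPS and LPS+Dex.

**Pausing index.** For each transcript (after collapsing transcripts with
identical 5' ends to a single model) the promoter window is −200/+500
around the TSS in transcript orientation and the body runs from +500 to the
3' end. With per-base densities d scaled to per-million library units,

    PI = log(1 + d_promoter) / log(1 + d_body)

computed on untreated Pol II coverage. PI > 1 is paused, PI < 0.8
non-paused, the band between is ambiguous. Transcripts whose promoter does
not overlap an LPS-condition Pol II peak are flagged ineligible.

**Cistromes.** Replicate peak sets are merged by union; Venn partitions
count, per side, peaks overlapping the other set by ≥ 1 nt; peaks are
annotated to promoter/exon/intron/downstream/distal by summit position;
genes associate with peaks through a gene-span ± 100 kb window;
class-conditional promoter-occupancy fractions carry exact
(Clopper–Pearson) binomial intervals. Metagene matrices (−200..+1500, 10-nt
bins) and mean profiles with SEM and t-based 95% bands summarize coverage.

## Worked example

```r
library(grpause)
report <- run_pipeline(pipeline_config(seed = 1, synth = list(n_genes = 300)))
print(report)
```

which prints (seed 1):

```
run_report (seed 1 , synthetic mode)
  gene sets: 74 induced, 32 dex-repressed, 42 dex-insensitive
  repressed-set transcripts: 8 paused, 23 non-paused, 1 ambiguous
  NELF occupancy paused_U:      8/8 = 100.0% (95% CI 63.1-100.0)
  NELF occupancy paused_LD:     7/8 = 87.5% (95% CI 47.3-99.7)
  NELF occupancy non_paused_U:  8/23 = 34.8% (95% CI 16.4-57.3)
  NELF occupancy non_paused_LD: 8/23 = 34.8% (95% CI 16.4-57.3)
```

Reading it: of 74 genes the exact test calls LPS-induced (> 1.5-fold, FDR
< 0.1), 32 are attenuated > 1.3-fold by Dex. Among eligible transcripts of
those repressed genes, 8 are paused (PI > 1) and 23 non-paused (PI < 0.8).
NELF occupies nearly all paused promoters but only about a third of
non-paused ones, in both the untreated and LPS+Dex states — the
class-specific NELF signature the pipeline is designed to expose. With
`outdir` set, every intermediate (GTF, bedGraph, narrowPeak, TSV tables,
`report.json`) is persisted and the report is byte-reproducible from the
same config and seed.

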