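# Seeded synthetic-data generator: gene models, Pol2/NELF coverage, peak
# sets for GR/p65/Pol2/NELF/BRD4, and NB count matrices, all carrying ground
# truth for downstream validation.
#
# Every artifact draws from its own RNG stream derived from (seed, artifact
# name), so adding artifacts never perturbs existing ones and a single seed
# reproduces everything byte-identically.

#' Parameters of the synthetic-data generator
#'
#' The defaults encode the experimental conditions the pipeline is meant to
#' recover: a pause site ~50 nt downstream of the TSS, 24% paused / 66%
#' non-paused transcripts among glucocorticoid-repressed genes, NELF
#' promoter occupancy probabilities of 86.3% (paused) vs 31.7% (non-paused)
#' in the untreated state and 83.6%/33.2% under LPS+Dex, >1.5-fold LPS
#' induction and >1.3-fold Dex attenuation of designated gene subsets.
#' Probabilities for the 1 h (evicted) and 3 h (reloaded) NELF timepoints
#' are free parameters of the generator, as are all density levels.
#'
#' @param n_genes Number of genes to place.
#' @param n_chroms Number of chromosomes; sizes are derived from
#'   `gene_spacing` and the gene length range.
#' @param gene_length_range Min/max gene length in nt (min must exceed 600
#'   so the +500 gene-body window is non-empty).
#' @param gene_spacing Distance between consecutive gene starts; the default
#'   keeps genes at least two 100-kb association flanks apart.
#' @param fraction_paused,fraction_nonpaused Class fractions; the remainder
#'   is generated with promoter density equal to body density (pausing index
#'   near 1, the ambiguous zone).
#' @param fraction_induced Fraction of genes induced by LPS. Kept below the
#'   TMM log-ratio trim fraction (0.30) so the normalization the pipeline
#'   prescribes remains consistent: with more one-sided differential genes
#'   than the trim removes, the trimmed mean retains induced genes and
#'   under-corrects fold changes. Real transcriptomes sit far below this
#'   (hundreds of induced genes among >10,000 expressed).
#' @param fraction_dex_repressed Fraction of induced genes whose induction
#'   is attenuated by Dex (default 201/597).
#' @param multi_tx_fraction Fraction of genes carrying 2-3 transcripts that
#'   share a 5' end but differ at the 3' end (exercises TSS collapsing).
#' @param pause_site_offset Pause-peak center, nt downstream of the TSS.
#' @param pause_peak_width Width of the promoter Pol2 bump; the bump is a
#'   discretized Gaussian with sd `pause_peak_width/4`.
#' @param promoter_to_body_ratio Mean promoter-window density over mean body
#'   density for paused genes in the untreated condition.
#' @param body_density_u Paused-gene body density (reads/base) untreated.
#' @param nonpaused_density_u Non-paused gene body density untreated;
#'   non-paused promoters carry `nonpaused_promoter_factor` times the body
#'   density, putting their pausing index well below the 0.8 threshold.
#' @param nonpaused_promoter_factor See above.
#' @param background_density Off-gene / NELF body background (reads/base).
#' @param lps_body_gain Multiplicative gain of body density under LPS.
#' @param dex_body_attenuation Factor by which Dex attenuates the LPS body
#'   gain (LPS+Dex body density = LPS level / attenuation).
#' @param lps_promoter_gain Additional Pol2 promoter loading under LPS (and
#'   retained under LPS+Dex) at paused genes.
#' @param nelf_prob_paused,nelf_prob_nonpaused Named per-condition
#'   Bernoulli probabilities of a promoter NELF peak, conditions
#'   `U` (untreated), `L` (LPS 1 h), `L3` (LPS 3 h), `LD` (LPS+Dex).
#' @param noise Poisson-sample coverage (`TRUE`) or emit expected densities
#'   directly (`FALSE`; used to check label recovery absent noise).
#' @param nb_dispersion Negative-binomial dispersion of the count matrix.
#' @param baseline_mean Median untreated expression level (counts).
#' @param induction_fold,attenuation_fold The fold thresholds the gene-set
#'   derivation applies downstream; generated true folds always exceed them.
#' @param induction_log2fc_range,attenuation_log2fc_range Uniform ranges
#'   from which per-gene true log2 folds are drawn.
#' @param n_background_gre Genome-wide GRE-like loci bound by GR whenever
#'   Dex is present, independent of LPS.
#' @param n_background_kb Genome-wide NF-kB-like loci bound by p65 whenever
#'   LPS is present.
#' @param kb_sites_per_gene Range (min, max) of NF-kB sites placed within
#'   the 100-kb window of each induced gene; for Dex-repressed genes these
#'   become GR/p65 tethering co-peaks under LPS+Dex.
#' @param peak_width Width of generated peaks (nt).
#' @param replicate_dropout Probability that replicate 2 misses a peak
#'   present in replicate 1.
#' @param replicate_jitter_sd SD (nt) of the coordinate jitter applied to
#'   replicate 2.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(n_genes = 300L,
                         n_chroms = 4L,
                         gene_length_range = c(2000L, 6000L),
                         gene_spacing = 200000L,
                         fraction_paused = 0.24,
                         fraction_nonpaused = 0.66,
                         fraction_induced = 0.25,
                         fraction_dex_repressed = 201 / 597,
                         multi_tx_fraction = 0.3,
                         pause_site_offset = 50L,
                         pause_peak_width = 200L,
                         promoter_to_body_ratio = 4,
                         body_density_u = 0.5,
                         nonpaused_density_u = 0.3,
                         nonpaused_promoter_factor = 0.4,
                         background_density = 0.05,
                         lps_body_gain = 6,
                         dex_body_attenuation = 3,
                         lps_promoter_gain = 1.5,
                         nelf_prob_paused = c(U = 0.863, L = 0.15,
                                              L3 = 0.80, LD = 0.836),
                         nelf_prob_nonpaused = c(U = 0.317, L = 0.10,
                                                 L3 = 0.30, LD = 0.332),
                         noise = TRUE,
                         nb_dispersion = 0.05,
                         baseline_mean = 200,
                         induction_fold = 1.5,
                         attenuation_fold = 1.3,
                         induction_log2fc_range = c(log2(1.8), 3),
                         attenuation_log2fc_range = c(log2(1.6), 2),
                         n_background_gre = 120L,
                         n_background_kb = 150L,
                         kb_sites_per_gene = c(1L, 3L),
                         peak_width = 300L,
                         replicate_dropout = 0.1,
                         replicate_jitter_sd = 15) {
  p <- as.list(environment())
  stopifnot(p$n_genes >= 0,
            p$gene_length_range[1] > 600,
            p$fraction_paused >= 0, p$fraction_nonpaused >= 0,
            p$fraction_paused + p$fraction_nonpaused <= 1,
            p$fraction_induced >= 0, p$fraction_induced <= 1,
            p$fraction_dex_repressed >= 0, p$fraction_dex_repressed <= 1,
            all(c("U", "L", "L3", "LD") %in% names(p$nelf_prob_paused)),
            all(c("U", "L", "L3", "LD") %in% names(p$nelf_prob_nonpaused)))
  class(p) <- "synth_params"
  p
}

# Deterministic stream seed from (seed, artifact name): a polynomial string
# hash folded into the base seed, kept below 2^31.
stream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Evaluate code under the RNG stream (seed, name), restoring the caller's
# RNG state afterwards.
with_stream <- function(seed, name, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(stream_seed(seed, name))
  force(code)
}

#' Generate a synthetic genome annotation with ground-truth labels
#'
#' Places `n_genes` non-overlapping genes across the chromosomes,
#' `gene_spacing` apart, assigns each a pausing class (paused / non_paused /
#' ambiguous) and a sensitivity label (dex_repressed / dex_insensitive /
#' not_induced), draws per-condition NELF promoter occupancy, and positions
#' NF-kB sites (tethering sites for Dex-repressed genes) within each induced
#' gene's 100-kb window. A fraction of genes carry 2-3 transcripts sharing
#' their 5' end with distinct 3' ends.
#'
#' @param params A [synth_params()] list.
#' @param seed Integer seed; all outputs are a pure function of
#'   (params, seed).
#' @return A list with elements `transcripts` (a `GRanges` of transcript
#'   models with `transcript_id`/`gene_id` and seqlengths set), `truth`
#'   (per-gene `data.frame`: `gene_id`, `chrom`, `strand`, `gene_start`,
#'   `gene_end`, `tss`, `pausing_class`, `sensitivity`, `nelf_U`, `nelf_L`,
#'   `nelf_L3`, `nelf_LD`, `log2fc_induction`, `log2fc_attenuation`,
#'   `base_mean`), `kb_sites` (a `GRanges` of NF-kB sites with `gene_id`),
#'   `chrom_sizes`, `params` and `seed`.
#' @export
generate_genome <- function(params = synth_params(), seed = 1L) {
  p <- params
  n <- p$n_genes
  per_chrom <- if (n > 0) ceiling(n / p$n_chroms) else 1L
  chrom_size <- as.integer((per_chrom + 1L) * p$gene_spacing +
                             max(p$gene_length_range) + 2e5)
  chrom_sizes <- setNames(rep(chrom_size, p$n_chroms),
                          paste0("chr", seq_len(p$n_chroms)))
  if (n == 0L) {
    tx <- GRanges(seqlengths = chrom_sizes)
    truth <- data.frame(gene_id = character())
    return(structure(list(transcripts = tx, truth = truth,
                          kb_sites = GRanges(seqlengths = chrom_sizes),
                          chrom_sizes = chrom_sizes, params = p, seed = seed),
                     class = "synth_genome"))
  }
  with_stream(seed, "genome", {
    gene_id <- sprintf("G%04d", seq_len(n))
    chrom <- names(chrom_sizes)[((seq_len(n) - 1L) %% p$n_chroms) + 1L]
    slot <- (seq_len(n) - 1L) %/% p$n_chroms
    # jitter keeps the layout irregular while preserving the spacing floor
    offset <- 1e5 + slot * p$gene_spacing +
      round(runif(n, 0, 0.25 * p$gene_spacing))
    len <- round(runif(n, p$gene_length_range[1], p$gene_length_range[2]))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gstart <- as.integer(offset)
    gend <- as.integer(offset + len - 1L)
    tss <- ifelse(strand == "+", gstart, gend)

    classes <- sample(c("paused", "non_paused", "ambiguous"), n,
                      replace = TRUE,
                      prob = c(p$fraction_paused, p$fraction_nonpaused,
                               1 - p$fraction_paused - p$fraction_nonpaused))
    induced <- runif(n) < p$fraction_induced
    repressed <- induced & runif(n) < p$fraction_dex_repressed
    sensitivity <- ifelse(repressed, "dex_repressed",
                          ifelse(induced, "dex_insensitive", "not_induced"))

    nelf_p <- function(cond) {
      pr <- ifelse(classes == "paused", p$nelf_prob_paused[[cond]],
                   ifelse(classes == "non_paused",
                          p$nelf_prob_nonpaused[[cond]],
                          mean(c(p$nelf_prob_paused[[cond]],
                                 p$nelf_prob_nonpaused[[cond]]))))
      runif(n) < pr
    }
    nelf <- sapply(c("U", "L", "L3", "LD"), nelf_p)

    log2fc_ind <- ifelse(induced,
                         runif(n, p$induction_log2fc_range[1],
                               p$induction_log2fc_range[2]), 0)
    log2fc_att <- ifelse(sensitivity == "dex_repressed",
                         runif(n, p$attenuation_log2fc_range[1],
                               p$attenuation_log2fc_range[2]), 0)
    base_mean <- exp(rnorm(n, log(p$baseline_mean), 0.8))

    truth <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                        gene_start = gstart, gene_end = gend, tss = tss,
                        pausing_class = classes, sensitivity = sensitivity,
                        nelf_U = nelf[, "U"], nelf_L = nelf[, "L"],
                        nelf_L3 = nelf[, "L3"], nelf_LD = nelf[, "LD"],
                        log2fc_induction = log2fc_ind,
                        log2fc_attenuation = log2fc_att,
                        base_mean = base_mean,
                        stringsAsFactors = FALSE)

    # transcripts: 1 per gene, or 2-3 sharing the 5' end with distinct 3'
    multi <- runif(n) < p$multi_tx_fraction
    tx_rows <- lapply(seq_len(n), function(i) {
      k <- if (multi[i]) sample(2:3, 1) else 1L
      full <- gend[i] - gstart[i] + 1L
      lens <- c(full, round(full * sort(runif(k - 1L, 0.55, 0.9))))
      s <- if (strand[i] == "+") rep(gstart[i], k) else gend[i] - lens + 1L
      e <- if (strand[i] == "+") gstart[i] + lens - 1L else rep(gend[i], k)
      data.frame(chrom = chrom[i], start = s, end = e, strand = strand[i],
                 transcript_id = sprintf("%s.T%d", gene_id[i], seq_len(k)),
                 gene_id = gene_id[i])
    })
    txdf <- do.call(rbind, tx_rows)
    tx <- GRanges(txdf$chrom, IRanges(txdf$start, txdf$end),
                  strand = txdf$strand, transcript_id = txdf$transcript_id,
                  gene_id = txdf$gene_id)
    seqlevels(tx) <- names(chrom_sizes)
    seqlengths(tx) <- chrom_sizes
    tx <- sort(tx, ignore.strand = TRUE)

    # NF-kB sites in the 100-kb window of induced genes; for dex_repressed
    # genes these are the tethering sites GR joins under LPS+Dex
    kb_idx <- which(induced)
    kb_rows <- lapply(kb_idx, function(i) {
      k <- sample(seq(p$kb_sites_per_gene[1], p$kb_sites_per_gene[2]), 1)
      pos <- round(runif(k, max(1, gstart[i] - 9e4), gend[i] + 9e4))
      data.frame(chrom = chrom[i], start = pos, gene_id = gene_id[i])
    })
    kb <- if (length(kb_rows)) {
      kbdf <- do.call(rbind, kb_rows)
      GRanges(kbdf$chrom,
              IRanges(kbdf$start, kbdf$start + p$peak_width - 1L),
              gene_id = kbdf$gene_id, seqlengths = chrom_sizes)
    } else GRanges(seqlengths = chrom_sizes)

    structure(list(transcripts = tx, truth = truth, kb_sites = kb,
                   chrom_sizes = chrom_sizes, params = p, seed = seed),
              class = "synth_genome")
  })
}

#' @export
print.synth_genome <- function(x, ...) {
  cat(sprintf("synth_genome: %d genes, %d transcripts, %d chromosomes, seed %d\n",
              nrow(x$truth), length(x$transcripts), length(x$chrom_sizes),
              x$seed))
  invisible(x)
}

# Expected per-base density over one gene for a factor/condition. Returns a
# list(pos_start, lambda) in genomic coordinates covering the promoter
# flank through the gene end.
gene_lambda <- function(g, condition, factor, p) {
  plus <- g$strand == "+"
  flank <- 300L
  lo <- max(1L, if (plus) g$gene_start - flank else g$gene_start)
  hi <- if (plus) g$gene_end else g$gene_end + flank
  npos <- hi - lo + 1L
  # transcript-oriented offset of each base from the TSS (0 at the TSS)
  off <- if (plus) (lo:hi) - g$tss else g$tss - (lo:hi)
  lam <- rep(0, npos)
  body <- off >= 0 & off <= (g$gene_end - g$gene_start)
  prom <- off >= -200 & off < 500

  if (factor == "Pol2") {
    cond <- if (condition == "L3") "L" else condition
    cls <- g$pausing_class
    if (cls == "paused") {
      b <- switch(cond, U = p$body_density_u,
                  L = p$body_density_u * p$lps_body_gain,
                  LD = p$body_density_u * p$lps_body_gain /
                    p$dex_body_attenuation)
      lam[body] <- b
      # Gaussian bump at tss + pause_site_offset carrying the promoter load
      amp_mean <- p$promoter_to_body_ratio * p$body_density_u
      if (cond != "U") amp_mean <- amp_mean * p$lps_promoter_gain
      sdv <- p$pause_peak_width / 4
      bump <- exp(-(off - p$pause_site_offset)^2 / (2 * sdv^2))
      # scale so the mean added density over the 700-nt promoter window
      # equals amp_mean
      bump <- bump * (amp_mean * 700 / sum(bump[prom]))
      lam <- lam + bump
    } else if (cls == "non_paused") {
      b <- switch(cond, U = p$nonpaused_density_u,
                  L = p$nonpaused_density_u * p$lps_body_gain,
                  LD = p$nonpaused_density_u * p$lps_body_gain /
                    p$dex_body_attenuation)
      if (g$sensitivity == "not_induced") b <- p$nonpaused_density_u
      lam[body] <- b
      lam[prom & !body] <- b * p$nonpaused_promoter_factor
      lam[prom & body] <- b * p$nonpaused_promoter_factor
    } else { # ambiguous: promoter density equals body density
      b <- p$nonpaused_density_u
      lam[body | prom] <- b
    }
  } else if (factor == "NELF") {
    occupied <- switch(condition, U = g$nelf_U, L = g$nelf_L,
                       L3 = g$nelf_L3, LD = g$nelf_LD)
    lam[body] <- p$background_density
    if (isTRUE(occupied)) {
      sdv <- p$pause_peak_width / 4
      bump <- 3 * exp(-(off - p$pause_site_offset)^2 / (2 * sdv^2))
      lam <- lam + bump
    }
  } else {
    stop("unrecognized coverage factor: ", factor)
  }
  list(lo = lo, hi = hi, lambda = lam)
}

#' Generate a synthetic coverage track
#'
#' Produces per-base Pol2 or NELF coverage for one condition. Paused genes
#' carry a promoter-proximal Pol2 bump centered `pause_site_offset` nt past
#' the TSS in every condition plus condition-dependent body coverage (low
#' untreated, gained under LPS, attenuated back toward untreated under
#' LPS+Dex). Non-paused genes carry uniform signal-dependent coverage with a
#' depleted promoter. NELF is a promoter bump present per the ground-truth
#' occupancy draw for that condition over a low body background. With
#' `params$noise` the expected densities are Poisson-sampled.
#'
#' @param genome A [generate_genome()] result.
#' @param condition One of `"U"`, `"L"`, `"LD"`, `"L3"`.
#' @param factor `"Pol2"` or `"NELF"`.
#' @param seed Integer seed (defaults to the genome's).
#' @return A [coverage_track()].
#' @export
generate_coverage <- function(genome, condition = c("U", "L", "LD", "L3"),
                              factor = c("Pol2", "NELF"), seed = genome$seed) {
  condition <- match.arg(condition)
  factor <- match.arg(factor)
  p <- genome$params
  truth <- genome$truth
  name <- paste("coverage", factor, condition, sep = "_")
  with_stream(seed, name, {
    segs <- lapply(names(genome$chrom_sizes), function(chrom) {
      rows <- truth[truth$chrom == chrom, , drop = FALSE]
      if (nrow(rows)) rows <- rows[order(rows$gene_start), , drop = FALSE]
      pieces <- list()
      cursor <- 0L
      for (i in seq_len(nrow(rows))) {
        gl <- gene_lambda(rows[i, ], condition, factor, p)
        vals <- if (p$noise) rpois(length(gl$lambda), gl$lambda) else gl$lambda
        gap <- gl$lo - 1L - cursor
        pieces[[length(pieces) + 1L]] <- Rle(0, gap)
        pieces[[length(pieces) + 1L]] <- Rle(vals)
        cursor <- gl$hi
      }
      pieces[[length(pieces) + 1L]] <-
        Rle(0, genome$chrom_sizes[[chrom]] - cursor)
      do.call(c, pieces)
    })
    names(segs) <- names(genome$chrom_sizes)
    coverage_track(as(segs, "SimpleRleList"),
                   factor = factor, condition = condition)
  })
}

#' Generate a synthetic peak set
#'
#' Encodes the co-occupancy structure the cistrome analysis is meant to
#' detect: GR binds background GRE-like loci whenever Dex is present, and
#' under LPS+Dex additionally joins p65 at the NF-kB sites of Dex-repressed
#' genes (tethering); p65 binds NF-kB sites of induced genes plus background
#' kB loci whenever LPS is present, unaffected by Dex; Pol2 peaks cover the
#' promoters of paused genes in every condition and of induced non-paused
#' genes under LPS; NELF peaks follow the per-condition ground-truth
#' occupancy; BRD4 marks paused promoters constitutively and induced
#' promoters under LPS. Replicate 2 is replicate 1 with peaks dropped at
#' rate `replicate_dropout` and coordinates jittered with SD
#' `replicate_jitter_sd`.
#'
#' @param genome A [generate_genome()] result.
#' @param factor One of `"GR"`, `"p65"`, `"Pol2"`, `"NELF"`, `"BRD4"`.
#' @param condition One of `"U"`, `"L"`, `"LD"`, `"D"`, `"L3"`.
#' @param replicate 1 or 2.
#' @param seed Integer seed (defaults to the genome's).
#' @return A `GRanges` with `name`, `score`, `summit` columns and
#'   factor/condition/replicate labels in `metadata()`.
#' @export
generate_peaks <- function(genome, factor = c("GR", "p65", "Pol2", "NELF", "BRD4"),
                           condition = c("U", "L", "LD", "D", "L3"),
                           replicate = 1L, seed = genome$seed) {
  factor <- match.arg(factor)
  condition <- match.arg(condition)
  p <- genome$params
  truth <- genome$truth
  sizes <- genome$chrom_sizes

  tx_gr <- function(rows) {
    if (!nrow(rows)) return(GRanges(seqlengths = sizes))
    GRanges(rows$chrom, IRanges(rows$gene_start, rows$gene_end),
            strand = rows$strand, seqlengths = sizes)
  }
  prom_of <- function(rows, up = 100L, down = 300L) {
    if (!nrow(rows)) return(GRanges(seqlengths = sizes))
    g <- tx_gr(rows)
    clip_to_chrom(suppressWarnings(promoters(g, up, down)))
  }
  # background loci shared across conditions/replicates of a factor family
  background <- function(tag, n_loci) {
    with_stream(seed, tag, {
      chrom <- sample(names(sizes), n_loci, replace = TRUE)
      pos <- round(runif(n_loci, 1e4, sizes[chrom] - 1e4))
      sort(GRanges(chrom, IRanges(pos, pos + p$peak_width - 1L),
                   seqlengths = sizes), ignore.strand = TRUE)
    })
  }

  base <- switch(factor,
    GR = {
      if (!condition %in% c("D", "LD")) GRanges(seqlengths = sizes)
      else {
        gre <- background("gre_loci", p$n_background_gre)
        if (condition == "LD") {
          tether <- genome$kb_sites[
            genome$kb_sites$gene_id %in%
              truth$gene_id[truth$sensitivity == "dex_repressed"]]
          mcols(tether) <- NULL
          sort(c(gre, tether), ignore.strand = TRUE)
        } else gre
      }
    },
    p65 = {
      if (!condition %in% c("L", "LD", "L3")) GRanges(seqlengths = sizes)
      else {
        kb_bg <- background("kb_loci", p$n_background_kb)
        kb <- genome$kb_sites
        mcols(kb) <- NULL
        sort(c(kb_bg, kb), ignore.strand = TRUE)
      }
    },
    Pol2 = {
      if (condition %in% c("L", "L3", "LD")) {
        keep <- truth$pausing_class %in% c("paused", "ambiguous") |
          (truth$sensitivity != "not_induced" &
             (condition != "LD" | truth$sensitivity == "dex_insensitive"))
      } else {
        keep <- truth$pausing_class %in% c("paused", "ambiguous")
      }
      prom_of(truth[keep, , drop = FALSE])
    },
    NELF = {
      col <- switch(condition, U = "nelf_U", L = "nelf_L", L3 = "nelf_L3",
                    LD = "nelf_LD", D = "nelf_U")
      prom_of(truth[truth[[col]], , drop = FALSE], up = 50L, down = 250L)
    },
    BRD4 = {
      keep <- if (condition %in% c("L", "L3"))
        truth$pausing_class == "paused" | truth$sensitivity != "not_induced"
      else truth$pausing_class == "paused"
      prom_of(truth[keep, , drop = FALSE], up = 300L, down = 300L)
    })
  strand(base) <- "*"
  base <- sort(base, ignore.strand = TRUE)

  if (replicate > 1L) {
    base <- with_stream(seed, paste("rep2", factor, condition, sep = "_"), {
      keep <- runif(length(base)) >= p$replicate_dropout
      out <- base[keep]
      if (length(out) && p$replicate_jitter_sd > 0) {
        shift_by <- round(rnorm(length(out), 0, p$replicate_jitter_sd))
        out <- clip_to_chrom(suppressWarnings(shift(out, shift_by)))
      }
      sort(out, ignore.strand = TRUE)
    })
  }
  if (length(base)) {
    base$name <- sprintf("%s_%s_r%d_%d", factor, condition, replicate,
                         seq_along(base))
    base$score <- 0
    base$summit <- as.integer(width(base) %/% 2)
  } else {
    mcols(base) <- DataFrame(name = character(), score = numeric(),
                             summit = integer())
  }
  metadata(base) <- list(factor = factor, condition = condition,
                         replicate = as.integer(replicate))
  base
}

#' Generate a synthetic RNA-seq count matrix
#'
#' Negative-binomial counts per gene and sample under the design's
#' condition/genotype labels. Induced genes carry an expected LPS/untreated
#' fold of at least the induction threshold; Dex-repressed genes an expected
#' LPS/(LPS+Dex) fold of at least the attenuation threshold; Dex-insensitive
#' genes are unchanged by Dex. In a `KO` genotype (loss of the NELF
#' complex), paused Dex-repressed genes lose their attenuation, emulating
#' glucocorticoid resistance of the paused class.
#'
#' @param genome A [generate_genome()] result.
#' @param design A `data.frame` with columns `sample`, `condition`
#'   (`U`/`L`/`LD`) and `genotype` (`WT`/`KO`); see [synth_design()].
#' @param seed Integer seed (defaults to the genome's).
#' @return A list with `counts` (integer matrix, genes x samples) and
#'   `design`.
#' @export
generate_counts <- function(genome, design = synth_design(),
                            seed = genome$seed) {
  p <- genome$params
  truth <- genome$truth
  stopifnot(all(c("sample", "condition", "genotype") %in% names(design)),
            nrow(design) > 0)
  if (!all(design$condition %in% c("U", "L", "LD"))) {
    stop("design conditions must be U, L or LD")
  }
  tab <- table(design$condition, design$genotype)
  if (any(tab[tab > 0] < 2)) {
    stop("each condition/genotype group needs at least 2 replicates")
  }
  mu_for <- function(cond, genotype) {
    mu <- truth$base_mean
    ind <- truth$sensitivity != "not_induced"
    if (cond %in% c("L", "LD")) mu[ind] <- mu[ind] * 2^truth$log2fc_induction[ind]
    if (cond == "LD") {
      att <- truth$sensitivity == "dex_repressed"
      if (genotype == "KO") att <- att & truth$pausing_class != "paused"
      mu[att] <- mu[att] / 2^truth$log2fc_attenuation[att]
    }
    mu
  }
  with_stream(seed, "counts", {
    cols <- lapply(seq_len(nrow(design)), function(j) {
      mu <- mu_for(design$condition[j], design$genotype[j])
      if (p$nb_dispersion > 0) {
        rnbinom(length(mu), mu = mu, size = 1 / p$nb_dispersion)
      } else rpois(length(mu), mu)
    })
    counts <- do.call(cbind, cols)
    dimnames(counts) <- list(truth$gene_id, design$sample)
    list(counts = counts, design = design)
  })
}

#' A default RNA-seq design
#'
#' @param conditions Conditions to include.
#' @param reps Replicates per condition.
#' @param genotype Genotype label applied to all samples.
#' @return A design `data.frame`.
#' @export
synth_design <- function(conditions = c("U", "L", "LD"), reps = 3L,
                         genotype = "WT") {
  data.frame(
    sample = paste0(rep(conditions, each = reps), "_", genotype, "_",
                    seq_len(reps)),
    condition = rep(conditions, each = reps),
    genotype = genotype,
    replicate = rep(seq_len(reps), times = length(conditions)),
    stringsAsFactors = FALSE)
}

#' Write all synthetic artifacts of a genome to disk
#'
#' Emits the annotation (GTF), chromosome sizes (TSV), ground truth (TSV)
#' and a JSON record of parameters and seed.
#'
#' @param genome A [generate_genome()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transcripts(genome$transcripts, file.path(dir, "annotation.gtf"))
  write.table(data.frame(names(genome$chrom_sizes), genome$chrom_sizes),
              file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(genome$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rec <- list(seed = genome$seed,
              params = genome$params[!vapply(genome$params, is.function,
                                             logical(1))])
  jsonlite::write_json(rec, file.path(dir, "params.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
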