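# Configuration-driven orchestration: synthetic (or user-supplied) inputs
# through gene-set derivation, pausing classification, cistrome overlap and
# occupancy analysis, and metagene summaries, into a reproducible report.

#' Build a pipeline configuration
#'
#' @param seed Integer seed fanned out to every synthetic artifact.
#' @param synth A list of [synth_params()] overrides (synthetic mode), or
#'   `NULL` when `inputs` is given.
#' @param inputs A list of input paths (user-data mode): `annotation` (GTF),
#'   `chrom_sizes` (TSV), `counts` (TSV, first column gene id),
#'   `sample_sheet` (TSV: sample, condition, genotype), `coverage` (named
#'   list `<factor>_<condition>` of bedGraph paths) and `peaks` (named list
#'   `<factor>_<condition>` of narrowPeak paths). Or `NULL` in synthetic
#'   mode.
#' @param thresholds Gene-set thresholds: `induce_fold`, `attenuate_fold`,
#'   `sig_threshold`, `sig_mode`.
#' @param pausing A list of [pausing_params()] overrides.
#' @param metagene `span` and `bin` for the metagene stage.
#' @param reps Synthetic RNA-seq replicates per condition.
#' @param outdir Output directory for persisted intermediates, or `NULL` to
#'   keep everything in memory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, synth = list(), inputs = NULL,
                            thresholds = list(), pausing = list(),
                            metagene = list(), reps = 3L, outdir = NULL) {
  cfg <- list(seed = seed, synth = synth, inputs = inputs,
              thresholds = thresholds, pausing = pausing,
              metagene = metagene, reps = reps, outdir = outdir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Accepts a `pipeline_config`, a plain list, or a path to a YAML/JSON file.
#' All problems — unknown keys, out-of-range thresholds, missing slots — are
#' collected and reported together. Defaults are filled in and echoed in
#' the returned object.
#'
#' @param config Configuration (list or file path).
#' @return The validated, default-filled `pipeline_config` (invisible
#'   errors aggregated into a single `stop()` otherwise).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  errs <- character()
  known <- c("seed", "synth", "inputs", "thresholds", "pausing", "metagene",
             "reps", "outdir")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown config key(s): ",
                           paste(unknown, collapse = ", ")))
  }
  if (is.null(config$seed)) errs <- c(errs, "missing required key: seed")
  has_synth <- !is.null(config$synth)
  has_inputs <- !is.null(config$inputs)
  if (!has_synth && !has_inputs) {
    errs <- c(errs, "one of 'synth' or 'inputs' must be provided")
  }
  if (has_synth && has_inputs) {
    errs <- c(errs, "'synth' and 'inputs' are mutually exclusive")
  }
  th <- config$thresholds
  if (is.null(th)) th <- list()
  th_defaults <- list(induce_fold = 1.5, attenuate_fold = 1.3,
                      sig_threshold = 0.1, sig_mode = "fdr")
  unknown <- setdiff(names(th), names(th_defaults))
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown thresholds key(s): ",
                           paste(unknown, collapse = ", ")))
  }
  th <- utils::modifyList(th_defaults, th[names(th) %in% names(th_defaults)])
  if (th$induce_fold <= 1) errs <- c(errs, "induce_fold must exceed 1")
  if (th$attenuate_fold <= 1) errs <- c(errs, "attenuate_fold must exceed 1")
  if (th$sig_threshold <= 0 || th$sig_threshold >= 1) {
    errs <- c(errs, "sig_threshold must lie in (0, 1)")
  }
  if (!th$sig_mode %in% c("fdr", "raw_p")) {
    errs <- c(errs, "sig_mode must be 'fdr' or 'raw_p'")
  }
  pp <- tryCatch(do.call(pausing_params, as.list(config$pausing)),
                 error = function(e) {
                   errs <<- c(errs, paste0("pausing: ", conditionMessage(e)))
                   pausing_params()
                 })
  mg <- config$metagene
  if (is.null(mg)) mg <- list()
  mg <- utils::modifyList(list(span = c(-200L, 1500L), bin = 10L), mg)
  if ((mg$span[2] - mg$span[1]) %% mg$bin != 0) {
    errs <- c(errs, "metagene bin must divide the span length")
  }
  sp <- NULL
  if (has_synth) {
    sp <- tryCatch(do.call(synth_params, as.list(config$synth)),
                   error = function(e) {
                     errs <<- c(errs, paste0("synth: ", conditionMessage(e)))
                     synth_params()
                   })
  }
  if (has_inputs) {
    required <- c("annotation", "chrom_sizes", "counts", "sample_sheet",
                  "coverage", "peaks")
    missing <- setdiff(required, names(config$inputs))
    if (length(missing)) {
      errs <- c(errs, paste0("inputs missing slot(s): ",
                             paste(missing, collapse = ", ")))
    }
    needed_cov <- "Pol2_U"
    needed_peaks <- c("Pol2_L", "NELF_U", "NELF_LD", "GR_LD", "p65_LD")
    if (!is.null(config$inputs$coverage)) {
      miss <- setdiff(needed_cov, names(config$inputs$coverage))
      if (length(miss)) {
        errs <- c(errs, paste0("inputs$coverage missing slot(s): ",
                               paste(miss, collapse = ", ")))
      }
    }
    if (!is.null(config$inputs$peaks)) {
      miss <- setdiff(needed_peaks, names(config$inputs$peaks))
      if (length(miss)) {
        errs <- c(errs, paste0("inputs$peaks missing slot(s): ",
                               paste(miss, collapse = ", ")))
      }
    }
  }
  if (length(errs)) {
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "))
  }
  out <- pipeline_config(seed = as.integer(config$seed),
                         synth = if (has_synth) sp else NULL,
                         inputs = config$inputs,
                         thresholds = th, pausing = pp, metagene = mg,
                         reps = if (!is.null(config$reps))
                           as.integer(config$reps) else 3L,
                         outdir = config$outdir)
  out
}

# Derive per-gene pausing classes from eligible transcript-level results.
gene_classes <- function(results, gene_ids) {
  sel <- results[results$gene_id %in% gene_ids & results$eligible, ,
                 drop = FALSE]
  cls <- tapply(sel$pi_class, sel$gene_id, function(x) {
    if (any(x == "paused")) "paused"
    else if (any(x == "non_paused")) "non_paused"
    else if (any(x == "ambiguous")) "ambiguous"
    else "undefined"
  })
  split(names(cls), unname(cls))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic generation (or input loading), gene-set
#' derivation from the count matrix, pausing-index computation and
#' classification on untreated Pol2 coverage with the LPS Pol2-peak
#' eligibility filter, cistrome overlap and promoter-occupancy analysis,
#' and metagene summaries. The report is a pure function of the
#' configuration and seed.
#'
#' @param config A [pipeline_config()] (validated internally).
#' @return A list of class `run_report`: gene-set sizes and members,
#'   pausing crosstabs, Venn partitions, occupancy fractions with exact
#'   binomial intervals, metagene profile summaries, the echoed config,
#'   package version and seed. When `config$outdir` is set, intermediates
#'   are persisted there (TSV/BED/bedGraph/GTF/JSON) along with
#'   `report.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- validate_config(config)
  seed <- cfg$seed
  t0 <- Sys.time()
  stage <- function(msg) message(sprintf("[%5.1fs] %s",
                                         as.numeric(Sys.time() - t0, units = "secs"),
                                         msg))
  synth_mode <- !is.null(cfg$synth)

  if (synth_mode) {
    stage("generating synthetic genome")
    genome <- generate_genome(cfg$synth, seed)
    tx <- genome$transcripts
    design <- synth_design(reps = cfg$reps)
    cm <- generate_counts(genome, design, seed)
    counts <- cm$counts
    stage("generating coverage and peaks")
    pol2_u <- generate_coverage(genome, "U", "Pol2", seed)
    peaks <- list(
      Pol2_L = union_replicates(generate_peaks(genome, "Pol2", "L", 1, seed),
                                generate_peaks(genome, "Pol2", "L", 2, seed)),
      NELF_U = union_replicates(generate_peaks(genome, "NELF", "U", 1, seed),
                                generate_peaks(genome, "NELF", "U", 2, seed)),
      NELF_LD = union_replicates(generate_peaks(genome, "NELF", "LD", 1, seed),
                                 generate_peaks(genome, "NELF", "LD", 2, seed)),
      GR_D = union_replicates(generate_peaks(genome, "GR", "D", 1, seed),
                              generate_peaks(genome, "GR", "D", 2, seed)),
      GR_LD = union_replicates(generate_peaks(genome, "GR", "LD", 1, seed),
                               generate_peaks(genome, "GR", "LD", 2, seed)),
      p65_LD = union_replicates(generate_peaks(genome, "p65", "LD", 1, seed),
                                generate_peaks(genome, "p65", "LD", 2, seed)))
    cov_tracks <- list(Pol2_U = pol2_u,
                       Pol2_L = generate_coverage(genome, "L", "Pol2", seed),
                       Pol2_LD = generate_coverage(genome, "LD", "Pol2", seed),
                       NELF_U = generate_coverage(genome, "U", "NELF", seed))
  } else {
    stage("loading inputs")
    chrom_sizes <- read_chrom_sizes(cfg$inputs$chrom_sizes)
    tx <- read_transcripts(cfg$inputs$annotation, chrom_sizes)
    ss <- read.table(cfg$inputs$sample_sheet, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    ctab <- read.table(cfg$inputs$counts, header = TRUE, sep = "\t",
                       row.names = 1, check.names = FALSE)
    counts <- as.matrix(ctab)
    design <- ss
    peaks <- lapply(cfg$inputs$peaks, read_peaks)
    cov_tracks <- lapply(names(cfg$inputs$coverage), function(nm) {
      read_bedgraph(cfg$inputs$coverage[[nm]], chrom_sizes)
    })
    names(cov_tracks) <- names(cfg$inputs$coverage)
    pol2_u <- cov_tracks$Pol2_U
    genome <- NULL
  }

  stage("deriving gene sets")
  cond <- design$condition[match(colnames(counts), design$sample)]
  de_lu <- de_test(counts, cond, c("L", "U"))
  de_lld <- de_test(counts, cond, c("L", "LD"))
  th <- cfg$thresholds
  sets <- derive_gene_sets(de_lu, de_lld, induce_fold = th$induce_fold,
                           attenuate_fold = th$attenuate_fold,
                           sig_threshold = th$sig_threshold,
                           sig_mode = th$sig_mode)

  stage("computing pausing indices")
  ctx <- collapse_transcripts(tx)
  res <- compute_pausing_index(pol2_u, ctx, cfg$pausing)
  res <- filter_by_promoter_peaks(res, peaks$Pol2_L)
  crosstab <- list(dex_repressed = crosstab_pi(sets$dex_repressed, res),
                   dex_insensitive = crosstab_pi(sets$dex_insensitive, res))

  stage("cistrome analysis")
  venns <- list(
    GR_LD_vs_p65_LD = venn_partition(peaks$GR_LD, peaks$p65_LD,
                                     label_a = "GR_LD", label_b = "p65_LD"),
    GR_D_vs_GR_LD = venn_partition(peaks$GR_D, peaks$GR_LD,
                                   label_a = "GR_D", label_b = "GR_LD"))
  classes <- gene_classes(res, sets$dex_repressed)
  occupancy <- list()
  for (cl in c("paused", "non_paused")) {
    for (cc in c("U", "LD")) {
      key <- paste(cl, cc, sep = "_")
      ids <- classes[[cl]]
      occupancy[[key]] <- if (length(ids)) {
        promoter_occupancy_fraction(ids, res, peaks[[paste0("NELF_", cc)]])
      } else list(k = 0L, n = 0L, fraction = NA_real_,
                  ci_low = NA_real_, ci_high = NA_real_)
    }
  }
  # tethering enrichment: GR/p65 co-occupancy near repressed genes vs
  # genome-wide
  repressed_tx <- ctx[ctx$gene_id %in% sets$dex_repressed]
  assoc <- gene_window_association(peaks$GR_LD, repressed_tx)
  gw_frac <- if (length(peaks$GR_LD)) {
    venns$GR_LD_vs_p65_LD$shared_a / venns$GR_LD_vs_p65_LD$total_a
  } else NA_real_
  near_idx <- unique(assoc$peak_index)
  near_frac <- if (length(near_idx)) {
    mean(overlapsAny(peaks$GR_LD[near_idx], peaks$p65_LD,
                     ignore.strand = TRUE))
  } else NA_real_

  stage("metagene summaries")
  mg <- cfg$metagene
  elig_tx <- ctx[ctx$transcript_id %in%
                   res$transcript_id[res$eligible &
                                       res$gene_id %in% sets$dex_repressed]]
  metagene <- NULL
  if (length(elig_tx)) {
    mats <- lapply(cov_tracks[grep("^Pol2_", names(cov_tracks))],
                   function(trk) binned_matrix(trk, elig_tx,
                                               span = mg$span, bin = mg$bin))
    mats <- lapply(mats, order_by_pi, results = res)
    cap <- equalize_scales(mats)
    profiles <- lapply(mats, mean_profile)
    metagene <- list(n_rows = nrow(mats[[1]]), n_bins = ncol(mats[[1]]),
                     display_cap = cap,
                     profile_peak = vapply(profiles, function(pr)
                       pr$bin_center[which.max(pr$mean)], numeric(1)))
  }

  report <- list(
    schema_version = 1L,
    package_version = as.character(utils::packageVersion("grpause")),
    seed = seed,
    mode = if (synth_mode) "synthetic" else "user_data",
    gene_sets = list(
      sizes = vapply(sets, length, integer(1)),
      members = sets),
    pausing = list(
      n_transcripts = nrow(res),
      n_eligible = sum(res$eligible),
      crosstab = crosstab),
    cistrome = list(
      venn = lapply(venns, function(v)
        v[c("label_a", "label_b", "total_a", "shared_a", "unique_a",
            "total_b", "shared_b", "unique_b")]),
      occupancy = occupancy,
      tether_enrichment = list(genome_wide = gw_frac,
                               near_dex_repressed = near_frac)),
    metagene = metagene,
    config = list(thresholds = th,
                  pausing = unclass(cfg$pausing),
                  metagene = mg, reps = cfg$reps,
                  synth = if (synth_mode) unclass(cfg$synth) else NULL))
  class(report) <- "run_report"

  if (!is.null(cfg$outdir)) {
    stage("persisting outputs")
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    if (synth_mode) {
      write_synth_genome(genome, file.path(cfg$outdir, "synth"))
      write.table(data.frame(gene_id = rownames(counts), counts,
                             check.names = FALSE),
                  file.path(cfg$outdir, "counts.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      for (nm in names(cov_tracks)) {
        write_bedgraph(cov_tracks[[nm]],
                       file.path(cfg$outdir, paste0(nm, ".bedGraph")))
      }
      for (nm in names(peaks)) {
        write_peaks(peaks[[nm]],
                    file.path(cfg$outdir, paste0(nm, ".narrowPeak")))
      }
    }
    write.table(de_lu, file.path(cfg$outdir, "de_L_vs_U.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(de_lld, file.path(cfg$outdir, "de_L_vs_LD.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_pausing_table(res, file.path(cfg$outdir, "pausing.tsv"),
                        file.path(cfg$outdir, "promoters.bed"))
    jsonlite::write_json(unclass(report),
                         file.path(cfg$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage("done")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed", x$seed, ",", x$mode, "mode)\n")
  s <- x$gene_sets$sizes
  cat(sprintf("  gene sets: %d induced, %d dex-repressed, %d dex-insensitive\n",
              s[["lps_induced"]], s[["dex_repressed"]],
              s[["dex_insensitive"]]))
  ct <- x$pausing$crosstab$dex_repressed$counts
  cat(sprintf("  repressed-set transcripts: %d paused, %d non-paused, %d ambiguous\n",
              ct[["paused"]], ct[["non_paused"]], ct[["ambiguous"]]))
  for (nm in names(x$cistrome$occupancy)) {
    o <- x$cistrome$occupancy[[nm]]
    if (!is.na(o$fraction)) {
      cat(sprintf("  NELF occupancy %-14s %d/%d = %.1f%% (95%% CI %.1f-%.1f)\n",
                  paste0(nm, ":"), o$k, o$n, 100 * o$fraction,
                  100 * o$ci_low, 100 * o$ci_high))
    }
  }
  invisible(x)
}
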