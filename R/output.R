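#' Write all analysis outputs to a directory
#'
#' Emits, per stage: the raw Ct TSV, the missing-value log and removed-gene
#' log (every filtering/imputation decision with gene and sample IDs), one
#' per-gene test TSV per normalization condition, the stability TSV, the
#' MAD-vs-p scatter coordinates CSV, the cross-scheme comparison JSON, the
#' simulation ground truth JSON (simulated inputs only), and a human-readable
#' `summary.md`. Output is deterministic: rerunning the same fit produces
#' byte-identical files.
#'
#' @param fit A [refgene_screen()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen <- function(fit, dir) {
  stopifnot(inherits(fit, "refgene_screen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_ct_table(fit$raw_ct, file.path(dir, "ct_raw.tsv"))
  tsv(attr(fit$expr, "missing_log"), "missing_log.tsv")
  tsv(fit$expr$removed, "removed_genes.tsv")
  for (lab in names(fit$tests)) {
    fn <- sprintf("tests_%s.tsv", gsub("[^A-Za-z0-9._-]+", "_", lab))
    tsv(as.data.frame(fit$tests[[lab]]), fn)
  }
  tsv(fit$stability, "stability.tsv")
  utils::write.csv(fit$stability[, c("gene", "mad", "anova_p_bh")],
                   file.path(dir, "screen_coordinates.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(fit$comparison)) {
    cmp <- fit$comparison
    jsonlite::write_json(
      list(schemes = cmp$schemes, regulated = cmp$regulated,
           regions = cmp$regions, unique = cmp$unique,
           union_n = cmp$union_n),
      file.path(dir, "comparison.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(fit$truth))
    write_sim_truth(fit$truth, file.path(dir, "truth.json"))
  writeLines(screen_summary_md(fit), file.path(dir, "summary.md"))
  invisible(dir)
}

screen_summary_md <- function(fit) {
  out <- c("# Reference-gene screening summary", "",
           sprintf("- input: %d genes x %d samples%s", nrow(fit$raw_ct$ct),
                   ncol(fit$raw_ct$ct),
                   if (is.null(fit$truth)) ""
                   else sprintf(" (simulated, seed %s)", fit$seed)),
           sprintf("- retained after pre-analytics: %d genes",
                   nrow(fit$expr$x)),
           sprintf("- removed: %s",
                   if (nrow(fit$expr$removed))
                     paste(sprintf("%s (%s)", fit$expr$removed$gene,
                                   fit$expr$removed$reason), collapse = ", ")
                   else "none"),
           "", "## Regulated genes per scheme", "")
  for (lab in names(fit$tests))
    out <- c(out, sprintf("- %s: %d regulated", lab,
                          sum(fit$tests[[lab]]$regulated, na.rm = TRUE)))
  inc <- fit$stability[isTRUE_vec(fit$stability$included), , drop = FALSE]
  out <- c(out, "", "## Stability screen", "",
           sprintf("- %d candidates passed the p >= %.2g floor",
                   nrow(fit$stability), fit$params$p_floor),
           sprintf("- top 3 by MAD: %s",
                   paste(utils::head(fit$stability$gene, 3L),
                         collapse = ", ")))
  if (nrow(inc)) {
    best <- inc[order(inc$stepwise_rank, inc$m_value), , drop = FALSE]
    out <- c(out,
             sprintf("- top 3 by geNorm stepwise rank: %s",
                     paste(utils::head(best$gene, 3L), collapse = ", ")),
             sprintf("- genes with M < 0.5: %d",
                     length(m_cutoff_filter(fit$stability))))
  }
  if (!is.null(fit$comparison)) {
    out <- c(out, "", "## Cross-scheme comparison", "",
             sprintf("- union of regulated sets: %d genes",
                     fit$comparison$union_n))
    for (s in fit$comparison$schemes)
      out <- c(out, sprintf("- unique to %s: %d", s,
                            length(fit$comparison$unique[[s]])))
  }
  if (!is.null(fit$focal))
    out <- c(out, "", sprintf("## Focal gene %s", fit$focal$gene), "",
             sprintf("- direction discordant across schemes: %s",
                     fit$focal$discordant))
  out
}

#' Default analysis configuration
#'
#' The configuration a bare run uses: the 7-point/23-sample design, the
#' 96-gene default archetype mix with 8 null genes planted to carry 2
#' unexplained missing cells each (so pre-analytic filtering has work to
#' do), array-mean QC on the batch-artifact gene, three normalization
#' conditions (none, drifting single reference, stable single reference),
#' the conventional thresholds (fold change 1.5, alpha 0.05, screen floor
#' p 0.05, missing tolerance 2) and a stable focal gene for the artifact
#' comparison.
#'
#' @return Nested list mirroring the YAML configuration schema.
#' @export
default_config <- function() {
  list(
    input = NULL,
    design = list(time_points_h = c(0, 1, 4, 9, 18, 27, 50),
                  replicates = c(3, 4, 4, 3, 3, 3, 3)),
    genes = list(n_genes = 96L, stable_noise_sd = 0.25,
                 null_noise_range = c(0.7, 1.5),
                 spike_amplitude = 7.70, drift_amplitude = 1.49),
    simulate = list(array_effect_sd = 0, planted_missing_genes = 8L,
                    planted_missing_cells = 2L),
    preprocess = list(max_unexplained = 2L, qc_genes = "batch_1",
                      qc_r_min = 0.5),
    schemes = list(list(mode = "none"),
                   list(mode = "single", references = "drift_1"),
                   list(mode = "single", references = "stable_1")),
    thresholds = list(fc_threshold = 1.5, alpha = 0.05, p_floor = 0.05,
                      missing_tolerance = 2L),
    focal_gene = "stable_3")
}

# recursively overlay user config on the defaults
merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(user[[nm]])) && nm != "schemes") {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the screening analysis from a configuration
#'
#' Reads a YAML configuration (or takes an equivalent nested list), overlays
#' it on [default_config()], runs [refgene_screen()] and optionally writes
#' the full output bundle. With `input` set in the configuration the Ct
#' matrix is read from TSV instead of simulated.
#'
#' @param config Path to a YAML file, or a nested list.
#' @param seed Integer seed for the simulation.
#' @param out_dir Output directory for [write_screen()] (skipped if `NULL`).
#' @return The [refgene_screen()] fit, invisibly.
#' @export
run_screen_config <- function(config = default_config(), seed = 1L,
                              out_dir = NULL) {
  if (is.character(config))
    config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  design <- study_design(unlist(cfg$design$time_points_h),
                         unlist(cfg$design$replicates))
  ct <- NULL
  archetypes <- NULL
  technical_missing <- NULL
  if (!is.null(cfg$input)) {
    ct <- read_ct_table(cfg$input)
  } else {
    archetypes <- study_archetypes(
      n_genes = cfg$genes$n_genes, design = design,
      stable_noise_sd = cfg$genes$stable_noise_sd,
      null_noise_range = unlist(cfg$genes$null_noise_range),
      spike_amplitude = cfg$genes$spike_amplitude,
      drift_amplitude = cfg$genes$drift_amplitude)
    n_plant <- cfg$simulate$planted_missing_genes
    if (n_plant > 0L) {
      nulls <- grep("^null_", names(archetypes), value = TRUE)
      if (n_plant > length(nulls))
        stop("more planted_missing_genes than null genes")
      technical_missing <- stats::setNames(
        rep(cfg$simulate$planted_missing_cells, n_plant),
        nulls[seq_len(n_plant)])
    }
  }
  schemes <- lapply(cfg$schemes, function(s) {
    norm_scheme(s$mode, unlist(s$references) %||% character(),
                literal_ct_geomean = isTRUE(s$literal_ct_geomean))
  })
  fit <- refgene_screen(
    ct = ct, design = design, archetypes = archetypes,
    schemes = schemes, seed = seed,
    array_effect_sd = cfg$simulate$array_effect_sd,
    technical_missing = technical_missing,
    fc_threshold = cfg$thresholds$fc_threshold,
    alpha = cfg$thresholds$alpha,
    p_floor = cfg$thresholds$p_floor,
    max_unexplained = cfg$preprocess$max_unexplained,
    missing_tolerance = cfg$thresholds$missing_tolerance,
    qc_genes = unlist(cfg$preprocess$qc_genes) %||% character(),
    qc_r_min = cfg$preprocess$qc_r_min,
    focal_gene = cfg$focal_gene)
  if (!is.null(out_dir))
    write_screen(fit, out_dir)
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
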