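#' Compare regulated-gene sets across normalization schemes
#'
#' Computes the regulated set under every scheme, all exclusive Venn-region
#' cardinalities by exact set algebra, and the genes unique to each scheme
#' (the artifact candidates when a scheme uses an unstable reference).
#'
#' @param tests Named list of [gene_tests()] results, one per scheme; all
#'   must share the same retained gene universe.
#' @param fc_threshold,alpha Regulation thresholds passed to
#'   [call_regulated()].
#' @return Object of class `scheme_comparison`: `schemes`, `regulated`
#'   (named list of gene sets), `regions` (data frame `region`, `n`,
#'   `genes`), `unique` (named list of genes exclusive to each scheme) and
#'   `union_n`. Disjoint region cardinalities sum to `union_n`.
#' @export
compare_schemes <- function(tests, fc_threshold = 1.5, alpha = 0.05) {
  if (is.null(names(tests)) || any(names(tests) == ""))
    stop("`tests` must be a named list (one entry per scheme)")
  universes <- lapply(tests, function(t) sort(t$gene))
  if (length(unique(universes)) != 1L)
    stop("gene universes differ across schemes")
  sets <- lapply(tests, call_regulated, fc_threshold = fc_threshold,
                 alpha = alpha)
  labs <- names(tests)
  k <- length(labs)
  all_genes <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) all_genes %in% s,
                       logical(length(all_genes)))
  if (length(all_genes) == 1L)
    membership <- matrix(membership, nrow = 1L,
                         dimnames = list(all_genes, labs))
  regions <- list()
  for (mask in seq_len(2^k - 1L)) {
    inside <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
    in_region <- if (length(all_genes)) {
      apply(membership, 1L, function(m) all(m == inside))
    } else logical(0)
    regions[[length(regions) + 1L]] <- data.frame(
      region = paste(labs[inside], collapse = " & "),
      n = sum(in_region),
      genes = paste(all_genes[in_region], collapse = ","),
      stringsAsFactors = FALSE)
  }
  regions <- do.call(rbind, regions)
  uniq <- lapply(seq_len(k), function(i) {
    setdiff(sets[[i]], unlist(sets[-i]))
  })
  names(uniq) <- labs
  structure(list(schemes = labs, regulated = sets, regions = regions,
                 unique = uniq, union_n = length(all_genes)),
            class = "scheme_comparison")
}

#' @export
print.scheme_comparison <- function(x, ...) {
  cat("scheme_comparison across:", paste(x$schemes, collapse = ", "), "\n")
  for (s in x$schemes)
    cat(sprintf("  %-28s %3d regulated (%d unique)\n", s,
                length(x$regulated[[s]]), length(x$unique[[s]])))
  cat("  union:", x$union_n, "genes; exclusive regions:\n")
  print(x$regions[, c("region", "n")], row.names = FALSE)
  invisible(x)
}

#' Fold-change trajectories of one gene under every scheme
#'
#' Aligns a focal gene's fold-change-vs-time curves across normalization
#' conditions, attaches the per-scheme ANOVA p and the t-test p at the time
#' of maximal change, and flags direction discordance: a gene called
#' changed (fold change beyond `fc_threshold`) upward under one scheme and
#' downward (or not changed) under another is the signature of a
#' normalization artifact.
#'
#' @param tables Named list of [expr_table]s, one per scheme.
#' @param gene Focal gene label (must be retained under every scheme).
#' @param fc_threshold Fold-change threshold defining a direction call.
#' @param var_equal Pooled-variance t-test (default).
#' @return Object of class `focal_trajectories`: `gene`, `trajectories`
#'   (data frame `scheme`, `time_h`, `fc`), `stats` (per-scheme `anova_p`,
#'   `max_fc_time`, `max_fc`, `ttest_p`, `direction`) and `discordant`
#'   (logical).
#' @export
focal_gene_trajectories <- function(tables, gene, fc_threshold = 1.5,
                                    var_equal = TRUE) {
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("`tables` must be a named list (one entry per scheme)")
  for (lab in names(tables))
    if (!gene %in% rownames(tables[[lab]]$x))
      stop(sprintf("gene '%s' missing under scheme '%s'", gene, lab))
  traj <- list()
  st <- list()
  for (lab in names(tables)) {
    tb <- tables[[lab]]
    tps <- sort(unique(tb$time_h))
    fc <- c(1, fold_change(tb, gene))
    traj[[lab]] <- data.frame(scheme = lab, time_h = tps, fc = unname(fc),
                              stringsAsFactors = FALSE)
    ap <- suppressWarnings(anova_per_gene(tb, gene))
    # direction comes from the trajectory itself; the t-test may degenerate
    # (e.g. zero residual variance) without affecting the direction call
    fc_nb <- fold_change(tb, gene)
    mag <- pmax(fc_nb, 1 / fc_nb)
    if (all(fc_nb == 1)) {
      peak_t <- tps[1L]; peak_mag <- 1; peak_fc <- 1
    } else {
      j <- which.max(mag)
      peak_t <- as.numeric(names(mag))[j]
      peak_mag <- mag[[j]]
      peak_fc <- fc_nb[[j]]
    }
    dir <- if (peak_mag < fc_threshold) "flat"
      else if (peak_fc > 1) "up" else "down"
    tt_p <- tryCatch(ttest_at_max(tb, gene, var_equal = var_equal)$p,
                     error = function(e) NA_real_)
    st[[lab]] <- data.frame(scheme = lab, anova_p = ap,
                            max_fc_time = peak_t, max_fc = peak_mag,
                            ttest_p = tt_p, direction = dir,
                            stringsAsFactors = FALSE)
  }
  st <- do.call(rbind, c(st, make.row.names = FALSE))
  structure(list(gene = gene,
                 trajectories = do.call(rbind, c(traj,
                                                 make.row.names = FALSE)),
                 stats = st,
                 discordant = length(unique(st$direction)) > 1L),
            class = "focal_trajectories")
}

#' @export
print.focal_trajectories <- function(x, ...) {
  cat(sprintf("focal gene '%s'%s\n", x$gene,
              if (x$discordant) " -- DIRECTION DISCORDANT across schemes"
              else ""))
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Run the full reference-gene screening analysis
#'
#' The package's main entry point. Either simulates a Ct matrix from a
#' [study_design()] and archetype set or takes a measured [ct_table], then
#' runs the pre-analytic pipeline, per-scheme normalization and
#' differential-regulation testing, the MAD + geNorm stability screen (on
#' the non-normalized condition), and the cross-scheme regulated-set
#' comparison. The result is a single object with `print()`, `summary()`
#' and `plot()` methods.
#'
#' @param ct A measured [ct_table], or `NULL` to simulate.
#' @param design The [study_design] (used for simulation).
#' @param archetypes Archetype list for simulation (default
#'   [study_archetypes()] sized by `n_genes`).
#' @param n_genes Number of simulated genes when `archetypes` is `NULL`.
#' @param schemes List of [norm_scheme]s to evaluate. A `"none"` scheme is
#'   always evaluated (it anchors the stability screen) even if not listed.
#' @param seed Integer seed controlling the simulation.
#' @param array_effect_sd Shared per-sample array-effect SD (cycles).
#' @param technical_missing Planted unexplained missing cells
#'   (see [simulate_ct()]).
#' @param fc_threshold,alpha Regulation-calling thresholds.
#' @param p_floor Stability-screen p floor ([candidate_screen()]).
#' @param max_unexplained Pre-analytic gene-removal threshold.
#' @param missing_tolerance geNorm missing-value tolerance.
#' @param qc_genes,qc_r_min Array-mean QC exclusion ([preprocess_ct()]).
#' @param overrides Sidecar missing-value overrides.
#' @param focal_gene Optional gene for cross-scheme trajectory comparison.
#' @param kw Also run Kruskal-Wallis per gene?
#' @param ttest Also run the t-test at maximal change per gene?
#' @return Object of class `refgene_screen` with components `expr` (the
#'   preprocessed non-normalized [expr_table]), `tables` and `tests` (per
#'   scheme), `stability`, `comparison`, `focal`, `truth` (simulations
#'   only), `raw_ct`, `seed` and `params`.
#' @examples
#' fit <- refgene_screen(n_genes = 24, seed = 42,
#'                       schemes = list(norm_scheme("none"),
#'                                      norm_scheme("single", "drift_1"),
#'                                      norm_scheme("single", "stable_1")))
#' summary(fit)
#' @export
refgene_screen <- function(ct = NULL, design = study_design(),
                           archetypes = NULL, n_genes = 96L,
                           schemes = list(norm_scheme("none")),
                           seed = 1L, array_effect_sd = 0,
                           technical_missing = NULL,
                           fc_threshold = 1.5, alpha = 0.05, p_floor = 0.05,
                           max_unexplained = 2L, missing_tolerance = 2L,
                           qc_genes = character(), qc_r_min = 0.5,
                           overrides = NULL, focal_gene = NULL,
                           kw = TRUE, ttest = TRUE) {
  cl <- match.call()
  truth <- NULL
  if (is.null(ct)) {
    if (is.null(archetypes))
      archetypes <- study_archetypes(n_genes, design)
    sim <- simulate_ct(design, archetypes, array_effect_sd = array_effect_sd,
                       seed = seed, technical_missing = technical_missing)
    ct <- sim$table
    truth <- sim$truth
  }
  stopifnot(inherits(ct, "ct_table"))
  if (inherits(schemes, "norm_scheme"))
    schemes <- list(schemes)
  labs <- vapply(schemes, `[[`, "", "label")
  if (anyDuplicated(labs))
    stop("duplicated scheme labels")
  names(schemes) <- labs
  if (!"none" %in% labs)
    schemes <- c(list(none = norm_scheme("none")), schemes)

  expr <- preprocess_ct(ct, max_unexplained = max_unexplained,
                        overrides = overrides, qc_genes = qc_genes,
                        qc_r_min = qc_r_min)
  tables <- lapply(schemes, function(s) normalize_expression(expr, s))
  tests <- lapply(tables, gene_tests, fc_threshold = fc_threshold,
                  alpha = alpha, kw = kw, ttest = ttest)
  stab <- stability_report(tables[["none"]], tests[["none"]],
                           p_floor = p_floor,
                           missing_tolerance = missing_tolerance)
  comparison <- if (length(tests) > 1L)
    compare_schemes(tests, fc_threshold = fc_threshold, alpha = alpha)
  else NULL
  focal <- if (!is.null(focal_gene))
    focal_gene_trajectories(tables, focal_gene, fc_threshold = fc_threshold)
  else NULL
  structure(list(call = cl, raw_ct = ct, truth = truth, expr = expr,
                 schemes = schemes, tables = tables, tests = tests,
                 stability = stab, comparison = comparison, focal = focal,
                 overall_mean = overall_mean_by_time(tables[["none"]]),
                 seed = seed,
                 params = list(fc_threshold = fc_threshold, alpha = alpha,
                               p_floor = p_floor,
                               max_unexplained = max_unexplained,
                               missing_tolerance = missing_tolerance,
                               qc_genes = qc_genes, qc_r_min = qc_r_min)),
            class = "refgene_screen")
}
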