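#' Per-gene one-way ANOVA across time points
#'
#' Classical fixed-effects one-way ANOVA of a gene's expression values
#' (x = 41 - Ct scale) grouped by time point, testing whether the gene is
#' differentially regulated anywhere in the time course.
#'
#' @param table An [expr_table].
#' @param gene Gene label.
#' @return The F-test p-value. Zero within-group variance with equal group
#'   means leaves F undefined: `NaN` is returned with a warning. Zero
#'   within-group variance with unequal means gives p = 0.
#' @export
anova_per_gene <- function(table, gene) {
  v <- gene_values(table, gene)
  anova_p(v$x, v$g)
}

anova_p <- function(x, g) {
  g <- factor(g)
  if (nlevels(g) < 2L)
    stop("need at least 2 time points")
  if (any(tabulate(g) < 2L))
    stop("each time point needs at least 2 samples")
  within <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  if (within == 0) {
    means <- tapply(x, g, mean)
    if (max(means) == min(means)) {
      warning("zero variance everywhere with equal means: F undefined")
      return(NaN)
    }
    return(0)
  }
  stats::oneway.test(x ~ g, var.equal = TRUE)$p.value
}

#' Per-gene Kruskal-Wallis test across time points
#'
#' Rank-based analogue of [anova_per_gene()] (with the standard tie
#' correction), robust to the distributional shape of the expression values.
#'
#' @inheritParams anova_per_gene
#' @return The chi-square approximation p-value; `NaN` with a warning when
#'   every value is tied (statistic undefined).
#' @export
kruskal_wallis_per_gene <- function(table, gene) {
  v <- gene_values(table, gene)
  kw_p(v$x, v$g)
}

kw_p <- function(x, g) {
  g <- factor(g)
  if (nlevels(g) < 2L)
    stop("need at least 2 time points")
  if (length(unique(x)) == 1L) {
    warning("all values tied: Kruskal-Wallis statistic undefined")
    return(NaN)
  }
  stats::kruskal.test(x, g)$p.value
}

gene_values <- function(table, gene) {
  stopifnot(inherits(table, "expr_table"))
  if (!gene %in% rownames(table$x))
    stop("gene not present: ", gene)
  list(x = table$x[gene, ], g = factor(table$time_h))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a family of p-values for multiple testing controlling the false
#' discovery rate: sorted ascending, `q(i) = min over j >= i of p(j) * m/j`,
#' capped at 1, returned in the original order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (`NA` allowed, passed
#'   through).
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' t-test at the time point of greatest change
#'
#' Identifies the time point maximizing the two-directional fold change
#' `max(FC, 1/FC)` (ties broken toward the earlier time point), then runs a
#' two-sided two-sample t-test between the baseline and that group.
#'
#' @inheritParams anova_per_gene
#' @param var_equal Pooled-variance t-test (default); `FALSE` for Welch.
#' @param baseline Baseline time point (default: earliest).
#' @return A list: `max_fc_time`, `max_fc` (fold up or down, >= 1), `fc`
#'   (signed fold change at that time) and `p`. When every fold change is
#'   exactly 1 the baseline itself is returned with `p = NA`. Zero variance
#'   in both groups is an error (degenerate t statistic).
#' @export
ttest_at_max <- function(table, gene, var_equal = TRUE, baseline = NULL) {
  stopifnot(inherits(table, "expr_table"))
  tps <- sort(unique(table$time_h))
  if (is.null(baseline))
    baseline <- tps[1L]
  fc <- fold_change(table, gene, baseline = baseline)
  mag <- pmax(fc, 1 / fc)
  if (all(fc == 1))
    return(list(max_fc_time = baseline, max_fc = 1, fc = 1, p = NA_real_))
  peak <- as.numeric(names(mag))[which.max(mag)]   # first max = earliest
  x <- table$x[gene, ]
  a <- x[table$time_h == baseline]
  b <- x[table$time_h == peak]
  if (length(a) < 2L || length(b) < 2L)
    stop("need >= 2 samples in baseline and peak groups")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("zero variance in both groups: t statistic degenerate")
  p <- stats::t.test(b, a, var.equal = var_equal)$p.value
  list(max_fc_time = peak, max_fc = max(mag), fc = unname(fc[as.character(peak)]),
       p = p)
}

#' Test every gene for differential regulation in the time course
#'
#' Runs one-way ANOVA (and optionally Kruskal-Wallis) per gene, adjusts the
#' ANOVA p-values across all genes with Benjamini-Hochberg (one family per
#' normalization condition), computes fold-change trajectories, locates the
#' time point of greatest change and its t-test, and calls regulated genes
#' (`max_fc >= fc_threshold` and adjusted p `< alpha`).
#'
#' @param table An [expr_table] (normalized or not).
#' @param fc_threshold Fold-change threshold for calling regulation.
#' @param alpha Significance threshold on the BH-adjusted ANOVA p.
#' @param kw Also run the Kruskal-Wallis test?
#' @param ttest Also run the t-test at the maximal change?
#' @param var_equal Pooled-variance t-test (default); `FALSE` for Welch.
#' @return A `gene_tests` data frame: `gene`, `anova_p`, `kw_p`,
#'   `anova_p_bh`, `max_fc`, `max_fc_time`, `ttest_p`, `regulated`, with the
#'   per-gene fold-change trajectories in `attr(, "fc_by_time")` and the
#'   scheme label in `attr(, "scheme")`.
#' @examples
#' sim <- simulate_ct(study_design(), study_archetypes(12), seed = 1)
#' res <- gene_tests(preprocess_ct(sim$table))
#' head(res)
#' @export
gene_tests <- function(table, fc_threshold = 1.5, alpha = 0.05,
                       kw = TRUE, ttest = TRUE, var_equal = TRUE) {
  stopifnot(inherits(table, "expr_table"))
  genes <- rownames(table$x)
  g <- factor(table$time_h)
  tps <- sort(unique(table$time_h))
  baseline <- tps[1L]
  fcm <- fold_change_matrix(table)
  non_base <- setdiff(colnames(fcm), as.character(baseline))
  res <- data.frame(gene = genes, anova_p = NA_real_, kw_p = NA_real_,
                    anova_p_bh = NA_real_, max_fc = NA_real_,
                    max_fc_time = NA_real_, ttest_p = NA_real_,
                    regulated = NA, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    x <- table$x[i, ]
    res$anova_p[i] <- suppressWarnings(anova_p(x, g))
    if (kw)
      res$kw_p[i] <- suppressWarnings(kw_p(x, g))
    fc <- fcm[i, non_base]
    mag <- pmax(fc, 1 / fc)
    if (all(fc == 1)) {
      res$max_fc[i] <- 1
      res$max_fc_time[i] <- baseline
    } else {
      j <- which.max(mag)
      res$max_fc[i] <- mag[j]
      res$max_fc_time[i] <- as.numeric(non_base[j])
      if (ttest) {
        b <- x[table$time_h == res$max_fc_time[i]]
        a <- x[table$time_h == baseline]
        res$ttest_p[i] <- tryCatch(
          stats::t.test(b, a, var.equal = var_equal)$p.value,
          error = function(e) NA_real_)
      }
    }
  }
  res$anova_p_bh <- bh_adjust(res$anova_p)
  res$regulated <- !is.na(res$anova_p_bh) & res$max_fc >= fc_threshold &
    res$anova_p_bh < alpha
  attr(res, "fc_by_time") <- fcm
  attr(res, "scheme") <- table$scheme
  attr(res, "fc_threshold") <- fc_threshold
  attr(res, "alpha") <- alpha
  class(res) <- c("gene_tests", "data.frame")
  res
}

#' Call significantly regulated genes
#'
#' A gene is regulated iff its maximal two-directional fold change reaches
#' `fc_threshold` **and** its BH-adjusted ANOVA p-value is below `alpha`
#' (adjustment done across all retained genes within one normalization
#' condition, see [gene_tests()]).
#'
#' @param results A [gene_tests()] data frame.
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Character vector of regulated gene labels.
#' @export
call_regulated <- function(results, fc_threshold = 1.5, alpha = 0.05) {
  stopifnot(is.data.frame(results))
  sel <- !is.na(results$anova_p_bh) & results$max_fc >= fc_threshold &
    results$anova_p_bh < alpha
  results$gene[sel]
}

#' Grand mean expression per time point
#'
#' Mean of x = 41 - Ct over all genes and samples of each time point; a
#' per-time-point global-transcription summary used to check that a single
#' gene's kinetics are not just overall drift in template amount.
#'
#' @param table An [expr_table].
#' @return Named numeric vector (time point -> grand mean).
#' @export
overall_mean_by_time <- function(table) {
  stopifnot(inherits(table, "expr_table"))
  if (nrow(table$x) == 0L)
    stop("empty table")
  grp <- time_groups(table$time_h)
  vapply(grp, function(idx) mean(table$x[, idx]), 0)
}
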