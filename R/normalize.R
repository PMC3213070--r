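#' Declare a normalization condition
#'
#' Three classes of condition are supported: no normalization, delta-Ct
#' against a single reference gene, and delta-Ct against the geometric mean
#' of two or more reference genes. On the log2-like `x = 41 - Ct` scale the
#' geometric mean of linear abundances is the arithmetic mean of x, which is
#' what `geometric_mean` mode subtracts; `literal_ct_geomean = TRUE` instead
#' takes a literal geometric mean of the reference Ct numbers (a numerically
#' eccentric reading kept for fidelity experiments).
#'
#' @param mode `"none"`, `"single"` or `"geometric_mean"`.
#' @param references Character vector of reference genes: empty for
#'   `"none"`, exactly 1 for `"single"`, >= 1 for `"geometric_mean"` (a
#'   single-element geometric mean is identical to `"single"`).
#' @param literal_ct_geomean Use the literal geometric mean of Ct numbers.
#' @param label Display label; derived from the scheme if omitted.
#' @return An object of class `norm_scheme`.
#' @examples
#' norm_scheme("single", "stable_1")
#' norm_scheme("geometric_mean", c("stable_1", "stable_2", "stable_3"))
#' @export
norm_scheme <- function(mode = c("none", "single", "geometric_mean"),
                        references = character(),
                        literal_ct_geomean = FALSE, label = NULL) {
  mode <- match.arg(mode)
  references <- as.character(references)
  if (anyDuplicated(references))
    stop("duplicated reference genes")
  n <- length(references)
  if (mode == "none" && n != 0L)
    stop("mode 'none' takes no reference genes")
  if (mode == "single" && n != 1L)
    stop("mode 'single' needs exactly one reference gene")
  if (mode == "geometric_mean" && n < 1L)
    stop("mode 'geometric_mean' needs at least one reference gene")
  if (is.null(label))
    label <- switch(mode, none = "none",
                    single = paste0("ref:", references),
                    geometric_mean = paste0("geomean:",
                                            paste(references, collapse = "+")))
  structure(list(mode = mode, references = references,
                 literal_ct_geomean = isTRUE(literal_ct_geomean),
                 label = label),
            class = "norm_scheme")
}

#' @export
print.norm_scheme <- function(x, ...) {
  cat("norm_scheme:", x$label,
      if (x$literal_ct_geomean) "(literal Ct geometric mean)" else "", "\n")
  invisible(x)
}

#' Normalize an expression table against reference genes
#'
#' Subtracts the per-sample reference signal from every gene (a delta-Ct on
#' the `x = 41 - Ct` scale, equivalent to dividing linear abundances by the
#' reference), then re-centers by adding back the across-sample mean of the
#' subtracted signal so the output stays on the original scale. The
#' re-centering constant is shared by all genes and samples, so it cancels in
#' every fold change and test statistic.
#'
#' @param table An [expr_table].
#' @param scheme A [norm_scheme].
#' @return An [expr_table] with the same axes, `scheme` set to the scheme's
#'   label.
#' @export
normalize_expression <- function(table, scheme) {
  stopifnot(inherits(table, "expr_table"), inherits(scheme, "norm_scheme"))
  if (scheme$mode == "none")
    return(table)
  absent <- setdiff(scheme$references, rownames(table$x))
  if (length(absent))
    stop("reference gene(s) not present in table: ",
         paste(absent, collapse = ", "))
  if (scheme$literal_ct_geomean) {
    ct_ref <- 41 - table$x[scheme$references, , drop = FALSE]
    if (any(ct_ref <= 0))
      stop("literal Ct geometric mean undefined for non-positive Ct")
    g <- exp(colMeans(log(ct_ref)))
    # Ct'(g,s) = Ct(g,s) - g(s) + mean(g)  =>  x' = x + g - mean(g)
    shift <- -(g - mean(g))
  } else {
    ref <- colMeans(table$x[scheme$references, , drop = FALSE])
    shift <- ref - mean(ref)
  }
  out <- table
  out$x <- sweep(table$x, 2L, shift)
  out$scheme <- scheme$label
  out
}

#' Fold change of a gene relative to the baseline time point
#'
#' `FC(g, t) = 2 ^ (mean x at t - mean x at baseline)`, i.e. the ratio of
#' geometric-mean abundances assuming one cycle per 2-fold. The baseline is
#' the earliest time point unless given.
#'
#' @param table An [expr_table].
#' @param gene Gene label.
#' @param t Time point(s) to report; all non-baseline time points if `NULL`.
#' @param baseline Baseline time point (default: earliest).
#' @return Named numeric vector of fold changes (`FC = 1` at equal means).
#' @examples
#' sim <- simulate_ct(study_design(), study_archetypes(12), seed = 1)
#' ex <- preprocess_ct(sim$table)
#' fold_change(ex, "spike_1", t = 4)
#' @export
fold_change <- function(table, gene, t = NULL, baseline = NULL) {
  stopifnot(inherits(table, "expr_table"))
  if (!gene %in% rownames(table$x))
    stop("gene not present: ", gene)
  tps <- sort(unique(table$time_h))
  if (is.null(baseline))
    baseline <- tps[1L]
  if (!baseline %in% table$time_h)
    stop("baseline time point absent from table")
  if (is.null(t))
    t <- setdiff(tps, baseline)
  if (!all(t %in% tps))
    stop("unknown time point(s): ", paste(setdiff(t, tps), collapse = ", "))
  x <- table$x[gene, ]
  base_mean <- mean(x[table$time_h == baseline])
  fc <- vapply(t, function(tp) 2^(mean(x[table$time_h == tp]) - base_mean), 0)
  stats::setNames(fc, t)
}

# genes x time-points matrix of fold changes vs baseline (baseline included,
# identically 1); rows genes, columns time points in order
fold_change_matrix <- function(table, baseline = NULL) {
  tps <- sort(unique(table$time_h))
  if (is.null(baseline))
    baseline <- tps[1L]
  grp <- time_groups(table$time_h)
  means <- vapply(grp, function(idx) rowMeans(table$x[, idx, drop = FALSE]),
                  numeric(nrow(table$x)))
  if (nrow(table$x) == 1L)
    means <- matrix(means, nrow = 1L,
                    dimnames = list(rownames(table$x), names(grp)))
  2^(means - means[, as.character(baseline)])
}
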