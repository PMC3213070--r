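#' Raw median absolute deviation
#'
#' Median of absolute deviations from the median, with **no** consistency
#' scaling (the 1.4826 factor that would convert it to an SD estimate for
#' Gaussian data is deliberately not applied). Because x = 41 - Ct is an
#' affine reflection of Ct, a gene's MAD is identical on the two scales.
#'
#' @param values Numeric vector (at least one value).
#' @return Non-negative raw MAD.
#' @examples
#' gene_mad(c(1, 2, 3, 4, 100))   # 1
#' @export
gene_mad <- function(values) {
  if (length(values) == 0L)
    stop("empty input")
  if (anyNA(values))
    stop("missing values not allowed")
  stats::mad(values, constant = 1)
}

#' Screen for candidate reference genes in the MAD / p-value plane
#'
#' Restricts to genes not significantly regulated in the *non-normalized*
#' data (BH-adjusted ANOVA p >= `p_floor`), attaches each gene's raw MAD
#' across all samples, and sorts by MAD ascending (ties broken by adjusted p
#' descending, i.e. the least-regulated gene first). Genes possessing low MAD
#' but high p are the reference-gene candidates.
#'
#' @param table The non-normalized [expr_table].
#' @param results [gene_tests()] output computed on that same table.
#' @param p_floor Minimum BH-adjusted ANOVA p for a gene to count as "not
#'   regulated" (default 0.05).
#' @return Data frame `gene`, `mad`, `anova_p_bh`, sorted; zero rows (with a
#'   warning) if no gene passes the floor.
#' @export
candidate_screen <- function(table, results, p_floor = 0.05) {
  stopifnot(inherits(table, "expr_table"), is.data.frame(results))
  if (!identical(table$scheme, "none"))
    warning("candidate screen is defined on the non-normalized table; ",
            "got scheme '", table$scheme, "'")
  keep <- !is.na(results$anova_p_bh) & results$anova_p_bh >= p_floor
  if (!any(keep)) {
    warning("no gene passes the p-value floor; empty candidate list")
    return(data.frame(gene = character(), mad = numeric(),
                      anova_p_bh = numeric(), stringsAsFactors = FALSE))
  }
  genes <- results$gene[keep]
  out <- data.frame(
    gene = genes,
    mad = apply(table$x[genes, , drop = FALSE], 1L, gene_mad),
    anova_p_bh = results$anova_p_bh[keep],
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$mad, -out$anova_p_bh), , drop = FALSE]
}

#' geNorm M stability values
#'
#' For each candidate gene i, `M(i)` is the mean over every other candidate j
#' of the sample standard deviation (n - 1 denominator) across samples of the
#' pairwise log-expression difference `x(i, s) - x(j, s)`. Lower M = more
#' stable. M is invariant to adding a constant to any single gene's profile
#' and to sample relabeling.
#'
#' @param table An [expr_table], or a plain numeric matrix (genes x samples).
#' @param candidates Candidate gene labels (>= 2), present in the table.
#' @return Named numeric vector of M values.
#' @examples
#' m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 3, 2, 4))
#' colnames(m) <- sprintf("t%dh_r1", c(0, 1, 4, 9))
#' genorm_m(m, c("a", "b", "c"))
#' @export
genorm_m <- function(table, candidates) {
  x <- if (inherits(table, "expr_table")) table$x else table
  if (!is.matrix(x))
    stop("`table` must be an expr_table or a numeric matrix")
  if (length(candidates) < 2L)
    stop("need at least 2 candidate genes")
  absent <- setdiff(candidates, rownames(x))
  if (length(absent))
    stop("candidate(s) not present: ", paste(absent, collapse = ", "))
  xs <- x[candidates, , drop = FALSE]
  # SD(x_i - x_j) via the covariance identity: var_i + var_j - 2 cov_ij
  cv <- stats::cov(t(xs))
  v <- diag(cv)
  sd_pair <- sqrt(pmax(outer(v, v, `+`) - 2 * cv, 0))
  diag(sd_pair) <- NA
  m <- rowMeans(sd_pair, na.rm = TRUE)
  stats::setNames(m, candidates)
}

#' geNorm stepwise-exclusion ranking of candidate reference genes
#'
#' First excludes candidates with more imputed/assigned cells than
#' `missing_tolerance` (their M would reflect imputation, not biology;
#' mirrors geNorm's exclusion of genes with excess missing values). Then
#' repeatedly computes M on the current candidate set and removes the gene
#' with the highest M, assigning it the current worst rank, until two genes
#' remain; the final pair is indistinguishable by construction (their M
#' values in a two-gene set are equal) and both get rank 1.
#'
#' @param table An [expr_table].
#' @param candidates Candidate gene labels.
#' @param missing_tolerance Maximum allowed count of `imputed_mean` +
#'   `assigned_ct40` cells per gene (default 2; exceeding it excludes the
#'   gene).
#' @return Data frame `gene`, `m_value` (full-included-set M),
#'   `stepwise_rank` (1 = most stable), `included`, `exclusion_reason`,
#'   sorted by rank with excluded genes last. Ties in the stepwise removal
#'   are broken toward the candidate listed first.
#' @export
genorm_rank <- function(table, candidates, missing_tolerance = 2L) {
  stopifnot(inherits(table, "expr_table"))
  absent <- setdiff(candidates, rownames(table$x))
  if (length(absent))
    stop("candidate(s) not present: ", paste(absent, collapse = ", "))
  prov <- table$provenance[candidates, , drop = FALSE]
  n_filled <- rowSums(matrix(prov %in% c("imputed_mean", "assigned_ct40"),
                             nrow = nrow(prov),
                             dimnames = dimnames(prov)))
  excluded <- candidates[n_filled > missing_tolerance]
  included <- setdiff(candidates, excluded)
  if (length(included) < 2L)
    stop("fewer than 2 candidates remain after missing-value exclusion")
  m_full <- genorm_m(table, included)
  rank_of <- stats::setNames(rep(NA_integer_, length(included)), included)
  current <- included
  while (length(current) > 2L) {
    m <- genorm_m(table, current)
    worst <- names(m)[which.max(m)]
    rank_of[worst] <- length(current)
    current <- setdiff(current, worst)
  }
  rank_of[current] <- 1L   # final pair shares rank 1
  out <- data.frame(
    gene = included,
    m_value = unname(m_full[included]),
    stepwise_rank = unname(rank_of[included]),
    included = TRUE,
    exclusion_reason = NA_character_,
    stringsAsFactors = FALSE)
  if (length(excluded)) {
    out <- rbind(out, data.frame(
      gene = excluded, m_value = NA_real_, stepwise_rank = NA_integer_,
      included = FALSE,
      exclusion_reason = sprintf("%d imputed/assigned cells (tolerance %d)",
                                 n_filled[excluded], missing_tolerance),
      stringsAsFactors = FALSE))
  }
  out <- out[order(!out$included, out$stepwise_rank, out$m_value), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter genes by the conventional M < 0.5 stability cutoff
#'
#' Strict inequality on the full-candidate-set M values; M = 0.5 exactly is
#' excluded.
#'
#' @param report A [genorm_rank()] report (or any data frame with `gene`,
#'   `m_value` and optionally `included`).
#' @param cutoff M cutoff (default 0.5).
#' @return Character vector of genes with `M < cutoff`.
#' @export
m_cutoff_filter <- function(report, cutoff = 0.5) {
  stopifnot(is.data.frame(report))
  inc <- if ("included" %in% names(report)) report$included else TRUE
  report$gene[inc & !is.na(report$m_value) & report$m_value < cutoff]
}

#' Combined stability report
#'
#' Merges the MAD/p screen and the geNorm stepwise ranking into one table
#' covering every screened candidate.
#'
#' @param table The non-normalized [expr_table].
#' @param results [gene_tests()] output on that table.
#' @param p_floor Screen p-value floor (see [candidate_screen()]).
#' @param missing_tolerance See [genorm_rank()].
#' @return Data frame `gene`, `mad`, `anova_p_bh`, `m_value`,
#'   `stepwise_rank`, `included`, `exclusion_reason`, sorted by MAD.
#' @export
stability_report <- function(table, results, p_floor = 0.05,
                             missing_tolerance = 2L) {
  screen <- candidate_screen(table, results, p_floor = p_floor)
  if (nrow(screen) < 2L) {
    screen$m_value <- numeric(nrow(screen))
    screen$stepwise_rank <- integer(nrow(screen))
    screen$included <- logical(nrow(screen))
    screen$exclusion_reason <- character(nrow(screen))
    return(screen)
  }
  gn <- genorm_rank(table, screen$gene, missing_tolerance = missing_tolerance)
  out <- merge(screen, gn, by = "gene", sort = FALSE)
  out <- out[order(out$mad), , drop = FALSE]
  rownames(out) <- NULL
  out
}
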