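#' Classify missing Ct values as biological or technical
#'
#' A missing cell is classified *biological* (physiological absence of
#' expression) if and only if its gene is undetected in **all** replicates of
#' a contiguous run of time points that touches the first or the last time
#' point of the design; every other missing cell is *technical* (unexplained,
#' presumed assay failure). This operationalizes the "absence of expression
#' at beginning or end of the time course" rule; case-by-case expert
#' judgment can be reproduced through per-cell overrides.
#'
#' @param table A [ct_table].
#' @param overrides Optional data frame with columns `gene`, `sample`,
#'   `class` (`"biological"` or `"technical"`) replacing the computed class
#'   for those cells (a sidecar annotation, see [read_missing_overrides()]).
#' @return Data frame with one row per missing cell: `gene`, `sample`,
#'   `time_h`, `class`. Zero rows when nothing is missing.
#' @examples
#' sim <- simulate_ct(study_design(), study_archetypes(12), seed = 1)
#' classify_missing(sim$table)
#' @export
classify_missing <- function(table, overrides = NULL) {
  stopifnot(inherits(table, "ct_table"))
  ct <- table$ct
  time_h <- table$time_h
  tps <- sort(unique(time_h))
  k <- length(tps)
  grp <- time_groups(time_h)
  out <- list()
  for (g in rownames(ct)) {
    miss <- is.na(ct[g, ])
    if (!any(miss)) next
    # time points at which every replicate is missing
    all_missing_tp <- vapply(grp, function(idx) all(miss[idx]), TRUE)
    bio_tp <- rep(FALSE, k)
    # contiguous runs of all-missing time points touching either edge
    i <- 1L
    while (i <= k && all_missing_tp[i]) { bio_tp[i] <- TRUE; i <- i + 1L }
    i <- k
    while (i >= 1L && all_missing_tp[i]) { bio_tp[i] <- TRUE; i <- i - 1L }
    cls <- ifelse(bio_tp[match(time_h[miss], tps)], "biological", "technical")
    out[[g]] <- data.frame(gene = g, sample = names(time_h)[miss],
                           time_h = unname(time_h[miss]), class = cls,
                           stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else
    data.frame(gene = character(), sample = character(),
               time_h = numeric(), class = character(),
               stringsAsFactors = FALSE)
  if (!is.null(overrides) && nrow(overrides) > 0L) {
    if (!all(c("gene", "sample", "class") %in% names(overrides)))
      stop("overrides need columns gene, sample, class")
    if (!all(overrides$class %in% c("biological", "technical")))
      stop("override class must be 'biological' or 'technical'")
    key <- paste(res$gene, res$sample)
    okey <- paste(overrides$gene, overrides$sample)
    hit <- match(key, okey)
    res$class[!is.na(hit)] <- overrides$class[hit[!is.na(hit)]]
  }
  res
}

#' Read a sidecar missing-value annotation file
#'
#' Tab-separated file with columns `gene`, `sample`, `class` providing manual
#' per-cell overrides of the automatic missing-value classification.
#'
#' @param path File path.
#' @return Data frame usable as the `overrides` argument of
#'   [classify_missing()].
#' @export
read_missing_overrides <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Impute missing Ct values according to their classification
#'
#' Biological missing cells are assigned the maximum cycle number, Ct = 40.
#' Technical missing cells receive the mean Ct of the gene's detected
#' replicates at the same time point (never a cross-time mean). Per-cell
#' provenance is recorded.
#'
#' @param table A [ct_table].
#' @param classification Output of [classify_missing()] covering every
#'   missing cell.
#' @param on_unrecoverable What to do when a technical cell has no detected
#'   replicate at its time point: `"error"` (default; such a gene should have
#'   been filtered) or `"keep"` (leave the cell missing and flag it, for use
#'   ahead of [filter_genes()]).
#' @return A list: `table` (the imputed [ct_table]) and `provenance`
#'   (character matrix: `"measured"`, `"imputed_mean"`, `"assigned_ct40"`, or
#'   `"unrecoverable"` under `on_unrecoverable = "keep"`).
#' @export
impute_and_flag <- function(table, classification = classify_missing(table),
                            on_unrecoverable = c("error", "keep")) {
  stopifnot(inherits(table, "ct_table"))
  on_unrecoverable <- match.arg(on_unrecoverable)
  ct <- table$ct
  prov <- matrix("measured", nrow(ct), ncol(ct), dimnames = dimnames(ct))
  n_missing <- sum(is.na(ct))
  if (n_missing != nrow(classification) ||
      (n_missing && !all(is.na(ct[cbind(classification$gene,
                                        classification$sample)]))))
    stop("classification must cover exactly the missing cells of `table`")
  if (n_missing == 0L)
    return(list(table = table, provenance = prov))
  for (i in seq_len(nrow(classification))) {
    g <- classification$gene[i]
    s <- classification$sample[i]
    if (classification$class[i] == "biological") {
      ct[g, s] <- 40
      prov[g, s] <- "assigned_ct40"
    } else {
      peers <- names(table$time_h)[table$time_h == table$time_h[s]]
      vals <- table$ct[g, setdiff(peers, s)]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0L) {
        if (on_unrecoverable == "error")
          stop(sprintf(
            "gene '%s': technical missing at t=%gh has no detected replicate (gene should have been filtered)",
            g, table$time_h[s]))
        prov[g, s] <- "unrecoverable"
      } else {
        ct[g, s] <- mean(vals)
        prov[g, s] <- "imputed_mean"
      }
    }
  }
  list(table = ct_table(ct, table$time_h, validate = FALSE),
       provenance = prov)
}

#' Filter genes with too many unexplained missing values
#'
#' Removes genes whose count of *technical* (unexplained) missing cells
#' reaches `max_unexplained` ("two or more" by default). Biological missing
#' cells never count toward removal.
#'
#' @param table A [ct_table].
#' @param classification Output of [classify_missing()].
#' @param max_unexplained Removal threshold (default 2).
#' @return A list: `table` (the filtered [ct_table]) and `removed` (data
#'   frame `gene`, `reason`, `detail`).
#' @export
filter_genes <- function(table, classification = classify_missing(table),
                         max_unexplained = 2L) {
  stopifnot(inherits(table, "ct_table"))
  if (max_unexplained < 1L)
    stop("`max_unexplained` must be >= 1")
  tech <- classification[classification$class == "technical", , drop = FALSE]
  counts <- table(factor(tech$gene, levels = rownames(table$ct)))
  drop <- names(counts)[counts >= max_unexplained]
  removed <- data.frame(
    gene = drop,
    reason = rep("unexplained_missing", length(drop)),
    detail = sprintf("%d technical missing cells (threshold %d)",
                     as.integer(counts[drop]), max_unexplained),
    stringsAsFactors = FALSE)
  keep <- setdiff(rownames(table$ct), drop)
  if (length(keep) == 0L)
    stop("all genes removed by missing-value filtering; degenerate input")
  list(table = ct_table(table$ct[keep, , drop = FALSE], table$time_h,
                        validate = FALSE),
       removed = removed)
}

#' The Laplace-corrected 41 - Ct expression transform
#'
#' Converts a fully imputed Ct table to the log2-like expression scale
#' `x = 41 - Ct`, reversing the ordering (higher x = more transcript) and
#' mapping the assigned maximum Ct of 40 to x = 1 rather than 0 (a
#' pseudocount of 1, so downstream ratios stay defined).
#'
#' @param table A [ct_table] with no missing cells.
#' @param provenance Optional per-cell provenance matrix (from
#'   [impute_and_flag()]).
#' @param removed Optional removal log (from [filter_genes()]).
#' @return An [expr_table].
#' @examples
#' m <- matrix(c(25, 40), 1, 2, dimnames = list("g", c("t0h_r1", "t4h_r1")))
#' ct_to_expression(ct_table(m))$x   # 16, 1
#' @export
ct_to_expression <- function(table, provenance = NULL, removed = NULL) {
  stopifnot(inherits(table, "ct_table"))
  if (anyNA(table$ct))
    stop("Ct table still contains missing cells; impute first")
  if (any(table$ct > 41))
    stop("Ct > 41 would yield non-positive expression")
  expr_table(41 - table$ct, table$time_h, provenance = provenance,
             removed = removed, scheme = "none")
}

#' QC: correlation of one gene's Ct with the per-sample mean Ct
#'
#' A gene tracking overall template quantity/quality should correlate
#' positively with the per-sample mean Ct over the remaining genes; a
#' batch-artifact gene (array-specific failures independent of the biology)
#' shows a correlation near zero. Used to vet suspect reference genes such as
#' an rRNA control with array-specific detection problems.
#'
#' @param table A [ct_table] (imputed, or with few enough missing cells that
#'   complete-observation correlation is meaningful).
#' @param gene Gene label.
#' @return Pearson correlation in `[-1, 1]`; the per-sample mean excludes the
#'   focal gene.
#' @export
qc_reference_vs_array_mean <- function(table, gene) {
  stopifnot(inherits(table, "ct_table"))
  if (!gene %in% rownames(table$ct))
    stop("gene not present: ", gene)
  if (ncol(table$ct) < 3L)
    stop("need at least 3 samples")
  v <- table$ct[gene, ]
  others <- table$ct[setdiff(rownames(table$ct), gene), , drop = FALSE]
  m <- colMeans(others, na.rm = TRUE)
  ok <- !is.na(v) & !is.na(m)
  if (stats::sd(v[ok]) == 0 || stats::sd(m[ok]) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(v[ok], m[ok])
}

#' Run the full pre-analytic pipeline
#'
#' classify missing values, impute (biological -> Ct 40, technical -> time
#' point mean), filter genes with too many unexplained missing values,
#' optionally exclude QC-flagged genes whose Ct does not track the per-sample
#' mean, and apply the 41 - Ct transform. Re-running the pipeline on a table
#' derived from its own output is a no-op.
#'
#' @param table A raw [ct_table].
#' @param max_unexplained Gene-removal threshold for technical missing cells.
#' @param overrides Optional sidecar classification overrides
#'   ([classify_missing()]).
#' @param qc_genes Genes to screen with [qc_reference_vs_array_mean()];
#'   those with correlation below `qc_r_min` are excluded.
#' @param qc_r_min Minimum acceptable correlation for `qc_genes`.
#' @return An [expr_table] whose `removed` log records filtered and
#'   QC-excluded genes; the missing-cell classification is kept in
#'   `attr(, "missing_log")`.
#' @examples
#' sim <- simulate_ct(study_design(), study_archetypes(12), seed = 1)
#' preprocess_ct(sim$table)
#' @export
preprocess_ct <- function(table, max_unexplained = 2L, overrides = NULL,
                          qc_genes = character(), qc_r_min = 0.5) {
  cls <- classify_missing(table, overrides = overrides)
  imp <- impute_and_flag(table, cls, on_unrecoverable = "keep")
  flt <- filter_genes(imp$table, cls, max_unexplained = max_unexplained)
  tbl <- flt$table
  prov <- imp$provenance[rownames(tbl$ct), , drop = FALSE]
  if (any(prov == "unrecoverable"))
    stop("unrecoverable technical missing cells survived filtering")
  removed <- flt$removed
  qc_genes <- intersect(qc_genes, rownames(tbl$ct))
  if (length(qc_genes)) {
    r <- vapply(qc_genes, function(g) qc_reference_vs_array_mean(tbl, g), 0)
    bad <- qc_genes[r < qc_r_min]
    if (length(bad)) {
      removed <- rbind(removed, data.frame(
        gene = bad, reason = "qc_array_mean",
        detail = sprintf("r = %.3f with per-sample mean Ct (min %.2f)",
                         r[bad], qc_r_min),
        stringsAsFactors = FALSE))
      keep <- setdiff(rownames(tbl$ct), bad)
      tbl <- ct_table(tbl$ct[keep, , drop = FALSE], tbl$time_h,
                      validate = FALSE)
      prov <- prov[keep, , drop = FALSE]
    }
  }
  out <- ct_to_expression(tbl, provenance = prov, removed = removed)
  attr(out, "missing_log") <- cls
  out
}
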