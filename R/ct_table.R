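#' Construct a Ct table
#'
#' A `ct_table` holds a genes x samples matrix of qPCR cycle-threshold (Ct)
#' values together with the per-sample time-point annotation of the study
#' design. Missing measurements (non-detection within the instrument's cycle
#' limit) are stored as `NA`.
#'
#' @param ct Numeric matrix, genes in rows (rownames are gene symbols),
#'   samples in columns (colnames are sample identifiers).
#' @param time_h Numeric vector of time points (hours), one per sample. If
#'   omitted, time points are parsed from sample identifiers of the form
#'   `t<hours>h_r<replicate>`.
#' @param validate Check the Ct range (present values must lie in (0, 40])?
#' @return An object of class `ct_table`: a list with elements `ct` (the
#'   matrix) and `time_h` (named numeric vector).
#' @examples
#' m <- matrix(c(24, 25, 26, 30, 31, 32), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("t0h_r1", "t0h_r2", "t4h_r1")))
#' ct_table(m)
#' @export
ct_table <- function(ct, time_h = NULL, validate = TRUE) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(ct)))
    stop("duplicated gene identifiers")
  if (anyDuplicated(colnames(ct)))
    stop("duplicated sample identifiers")
  if (is.null(time_h))
    time_h <- parse_sample_time(colnames(ct))
  if (length(time_h) != ncol(ct))
    stop("`time_h` must have one entry per sample")
  names(time_h) <- colnames(ct)
  if (validate) {
    v <- ct[!is.na(ct)]
    if (any(v <= 0 | v > 40))
      stop("Ct values must lie in (0, 40]; use NA for non-detection")
  }
  structure(list(ct = ct, time_h = time_h), class = "ct_table")
}

# sample ids of the form t<hours>h_r<replicate>, e.g. t4h_r2
parse_sample_time <- function(ids) {
  m <- regmatches(ids, regexec("^t([0-9]+(?:\\.[0-9]+)?)h_r[0-9]+$", ids))
  bad <- vapply(m, length, 1L) != 2L
  if (any(bad))
    stop("cannot parse time point from sample id(s): ",
         paste(ids[bad], collapse = ", "),
         " (expected t<hours>h_r<replicate>)")
  as.numeric(vapply(m, `[`, "", 2L))
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("ct_table: %d genes x %d samples, %d time points (%s h), %d missing cells\n",
              nrow(x$ct), ncol(x$ct), length(unique(x$time_h)),
              paste(sort(unique(x$time_h)), collapse = ", "),
              sum(is.na(x$ct))))
  invisible(x)
}

#' @export
dim.ct_table <- function(x) dim(x$ct)

#' Read / write a Ct table as TSV
#'
#' The on-disk dialect is tab-separated text with the gene symbol in the first
#' column (header `gene`) and one column per sample; missing values are the
#' literal token `NA`. Sample columns are named `t<hours>h_r<replicate>`.
#'
#' @param path File path.
#' @return `read_ct_table()` returns a [ct_table]; `write_ct_table()` returns
#'   `path` invisibly.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("Ct table must have a gene column plus at least one sample column")
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[-1L])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  ct_table(m)
}

#' @rdname read_ct_table
#' @param table A [ct_table].
#' @export
write_ct_table <- function(table, path) {
  stopifnot(inherits(table, "ct_table"))
  df <- data.frame(gene = rownames(table$ct), table$ct,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an expression table
#'
#' An `expr_table` holds fully imputed expression values on the log2-like
#' `x = 41 - Ct` scale, per-cell provenance flags, and the log of genes that
#' were removed before the transform. It is produced by [preprocess_ct()] (or
#' [ct_to_expression()]) and consumed by normalization, testing and stability
#' screening.
#'
#' @param x Numeric matrix of expression values (genes x samples), no missing
#'   cells.
#' @param time_h Per-sample time points (hours).
#' @param provenance Character matrix of the same shape with entries
#'   `"measured"`, `"imputed_mean"` or `"assigned_ct40"`.
#' @param removed Data frame logging removed genes (`gene`, `reason`,
#'   `detail`), possibly empty.
#' @param scheme Label of the normalization condition the values are under
#'   (`"none"` for an unnormalized table).
#' @return An object of class `expr_table`.
#' @export
expr_table <- function(x, time_h, provenance = NULL, removed = NULL,
                       scheme = "none") {
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric matrix")
  if (anyNA(x))
    stop("expression table must not contain missing cells")
  if (length(time_h) != ncol(x))
    stop("`time_h` must have one entry per sample")
  names(time_h) <- colnames(x)
  if (is.null(provenance)) {
    provenance <- matrix("measured", nrow(x), ncol(x), dimnames = dimnames(x))
  }
  stopifnot(identical(dim(provenance), dim(x)))
  if (is.null(removed))
    removed <- data.frame(gene = character(), reason = character(),
                          detail = character(), stringsAsFactors = FALSE)
  structure(list(x = x, time_h = time_h, provenance = provenance,
                 removed = removed, scheme = scheme),
            class = "expr_table")
}

#' @export
print.expr_table <- function(x, ...) {
  cat(sprintf("expr_table (x = 41 - Ct scale): %d genes x %d samples, scheme '%s'\n",
              nrow(x$x), ncol(x$x), x$scheme))
  n_imp <- sum(x$provenance != "measured")
  if (n_imp > 0L)
    cat(sprintf("  %d imputed/assigned cells\n", n_imp))
  if (nrow(x$removed) > 0L)
    cat(sprintf("  %d genes removed pre-transform\n", nrow(x$removed)))
  invisible(x)
}

#' @export
dim.expr_table <- function(x) dim(x$x)

# samples (column indices) belonging to each time point, in time order
time_groups <- function(time_h) {
  tps <- sort(unique(time_h))
  lapply(stats::setNames(tps, tps), function(tp) which(time_h == tp))
}
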