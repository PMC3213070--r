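#' @export
print.refgene_screen <- function(x, ...) {
  cat("refgene_screen analysis\n")
  cat(sprintf("  input: %d genes x %d samples (%s)\n",
              nrow(x$raw_ct$ct), ncol(x$raw_ct$ct),
              if (is.null(x$truth)) "measured" else
                sprintf("simulated, seed %s", x$seed)))
  cat(sprintf("  retained after pre-analytics: %d genes (%d removed)\n",
              nrow(x$expr$x), nrow(x$expr$removed)))
  cat("  schemes:", paste(names(x$schemes), collapse = ", "), "\n")
  for (lab in names(x$tests))
    cat(sprintf("    %-28s %3d regulated\n", lab,
                sum(x$tests[[lab]]$regulated, na.rm = TRUE)))
  inc <- x$stability[isTRUE_vec(x$stability$included), , drop = FALSE]
  cat(sprintf("  stability screen: %d candidates (p_bh >= %.2g), geNorm on %d\n",
              nrow(x$stability), x$params$p_floor, nrow(inc)))
  if (nrow(inc))
    cat("  top candidates (by MAD):",
        paste(utils::head(x$stability$gene, 3L), collapse = ", "), "\n")
  invisible(x)
}

isTRUE_vec <- function(v) !is.na(v) & v

#' Summarize a reference-gene screening analysis
#'
#' @param object A [refgene_screen()] fit.
#' @param top Number of top stability candidates to display.
#' @param ... Unused.
#' @return An object of class `summary.refgene_screen` (printed with the
#'   regulated counts per scheme, Venn regions, and the leading candidates).
#' @export
summary.refgene_screen <- function(object, top = 5L, ...) {
  reg_counts <- vapply(object$tests, function(t)
    sum(t$regulated, na.rm = TRUE), 0L)
  structure(list(fit = object, reg_counts = reg_counts, top = top),
            class = "summary.refgene_screen")
}

#' @export
print.summary.refgene_screen <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nRemoved genes:\n")
  if (nrow(fit$expr$removed)) print(fit$expr$removed, row.names = FALSE)
  else cat("  (none)\n")
  cat("\nTop stability candidates:\n")
  cols <- intersect(c("gene", "mad", "anova_p_bh", "m_value",
                      "stepwise_rank"), names(fit$stability))
  print(utils::head(fit$stability[, cols], x$top), row.names = FALSE,
        digits = 3)
  if (!is.null(fit$comparison)) {
    cat("\n")
    print(fit$comparison)
  }
  if (!is.null(fit$focal)) {
    cat("\n")
    print(fit$focal)
  }
  invisible(x)
}

#' Plot a reference-gene screening analysis
#'
#' `which = "screen"` draws the MAD-vs-adjusted-p scatter of the candidate
#' screen (low MAD + high p = reference-gene candidates; the conventional
#' p = 0.05 floor is dashed). `which = "trajectories"` draws the focal
#' gene's fold-change curves under every normalization scheme (requires
#' `focal_gene` to have been set). `which = "m_values"` draws the geNorm M
#' values in stepwise-rank order.
#'
#' @param x A [refgene_screen()] fit.
#' @param which One of `"screen"`, `"trajectories"`, `"m_values"`.
#' @param ... Passed to the underlying base-graphics call.
#' @return `x`, invisibly.
#' @export
plot.refgene_screen <- function(x, which = c("screen", "trajectories",
                                             "m_values"), ...) {
  which <- match.arg(which)
  if (which == "screen") {
    s <- x$stability
    if (!nrow(s)) stop("empty stability screen")
    graphics::plot(s$anova_p_bh, s$mad, xlab = "BH-adjusted ANOVA p",
                   ylab = "MAD (cycles)",
                   main = "Reference-gene candidate screen", ...)
    graphics::abline(v = x$params$p_floor, lty = 2)
    top <- utils::head(s, 3L)
    graphics::text(top$anova_p_bh, top$mad, top$gene, pos = 3, cex = 0.8)
  } else if (which == "trajectories") {
    if (is.null(x$focal))
      stop("no focal gene was set; rerun with `focal_gene = ...`")
    tr <- x$focal$trajectories
    labs <- unique(tr$scheme)
    graphics::matplot(
      x = unique(tr$time_h),
      y = vapply(labs, function(l) tr$fc[tr$scheme == l],
                 numeric(length(unique(tr$time_h)))),
      type = "b", pch = seq_along(labs), lty = 1, log = "y",
      xlab = "time (h)", ylab = "fold change vs t = 0 h",
      main = sprintf("%s under each normalization", x$focal$gene), ...)
    graphics::abline(h = 1, lty = 3)
    graphics::legend("topright", legend = labs, pch = seq_along(labs),
                     col = seq_along(labs), bty = "n", cex = 0.8)
  } else {
    s <- x$stability[isTRUE_vec(x$stability$included), , drop = FALSE]
    if (!nrow(s)) stop("no included geNorm candidates")
    s <- s[order(s$stepwise_rank), ]
    graphics::plot(seq_len(nrow(s)), s$m_value, xaxt = "n", type = "h",
                   xlab = "", ylab = "geNorm M",
                   main = "Candidate stability (lower M = more stable)", ...)
    graphics::axis(1, at = seq_len(nrow(s)), labels = s$gene, las = 2,
                   cex.axis = 0.7)
    graphics::abline(h = 0.5, lty = 2)
  }
  invisible(x)
}
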