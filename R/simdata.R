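#' Study design for a qPCR time course
#'
#' Describes the sampling layout of a time-course experiment: which time
#' points were sampled and how many biological replicates (animals) each one
#' has. The default reproduces a 7-point, 23-sample design over 0-50 h with
#' 4 replicates at 1 h and 4 h and 3 at every other point.
#'
#' @param time_points_h Strictly increasing non-negative time points (hours).
#' @param replicates Positive integer replicate count per time point.
#' @return An object of class `study_design` with fields `time_points_h`,
#'   `replicates`, `sample_ids` and `time_h` (per-sample time).
#' @examples
#' study_design()
#' @export
study_design <- function(time_points_h = c(0, 1, 4, 9, 18, 27, 50),
                         replicates = c(3, 4, 4, 3, 3, 3, 3)) {
  if (length(time_points_h) != length(replicates))
    stop("`time_points_h` and `replicates` must have the same length")
  if (any(time_points_h < 0) || any(diff(time_points_h) <= 0))
    stop("time points must be non-negative and strictly increasing")
  replicates <- as.integer(replicates)
  if (any(replicates < 1L))
    stop("each time point needs at least one replicate")
  ids <- unlist(mapply(function(tp, n) {
    sprintf("t%sh_r%d", format(tp, trim = TRUE), seq_len(n))
  }, time_points_h, replicates, SIMPLIFY = FALSE))
  time_h <- rep(time_points_h, replicates)
  names(time_h) <- ids
  structure(list(time_points_h = time_points_h, replicates = replicates,
                 sample_ids = ids, time_h = time_h),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study_design: %d time points (%s h), replicates (%s), %d samples\n",
              length(x$time_points_h),
              paste(x$time_points_h, collapse = ", "),
              paste(x$replicates, collapse = ", "),
              sum(x$replicates)))
  invisible(x)
}

#' Gene archetype for the Ct simulator
#'
#' An archetype defines the generative parameters of one simulated gene:
#' baseline Ct, a planted log2 fold-change trajectory relative to the first
#' time point, per-cell Gaussian noise (cycles), and an optional detection
#' threshold above which a measurement drops out (is recorded missing).
#'
#' Positive log2 fold change lowers Ct (more template amplifies earlier), at
#' the conventional 100% amplification efficiency of one cycle per 2-fold.
#'
#' @param name Gene label.
#' @param kind One of `"stable"`, `"spike"`, `"drift"`, `"null"`,
#'   `"dropout"`, `"batch_artifact"`. `stable` and `null` archetypes must
#'   have an all-zero trajectory.
#' @param baseline_ct Baseline Ct (cycles) at the first time point.
#' @param log2_trajectory Log2 fold change vs the first time point, one value
#'   per design time point.
#' @param noise_sd Per-cell Gaussian noise SD (cycles), >= 0.
#' @param dropout_ct_threshold Ct above which the cell is recorded missing;
#'   `NA` disables dropout.
#' @return An object of class `gene_archetype`.
#' @export
gene_archetype <- function(name, kind, baseline_ct, log2_trajectory,
                           noise_sd = 0, dropout_ct_threshold = NA_real_) {
  kind <- match.arg(kind, c("stable", "spike", "drift", "null", "dropout",
                            "batch_artifact"))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("`noise_sd` must be a single non-negative number")
  if (kind %in% c("stable", "null") && any(log2_trajectory != 0))
    stop(sprintf("archetype '%s' of kind '%s' must have an all-zero trajectory",
                 name, kind))
  structure(list(name = as.character(name), kind = kind,
                 baseline_ct = baseline_ct,
                 log2_trajectory = as.numeric(log2_trajectory),
                 noise_sd = noise_sd,
                 dropout_ct_threshold = dropout_ct_threshold),
            class = "gene_archetype")
}

#' Default archetype set emulating a 96-gene inflammation array
#'
#' Builds the default truth mix used throughout the package's simulations:
#' 3 stable reference candidates (low-noise, flat), 1 spike gene with a
#' 2^7.70 (~208-fold) burst at 4 h, 1 drifting pseudo-reference rising
#' 2^1.49 (~2.8-fold) to a peak at 18 h, 1 batch-artifact gene whose signal
#' is dominated by array-independent shifts, 2 dropout-prone low expressors
#' near the detection limit, and null genes for the remainder. Null genes
#' carry heterogeneous biological noise (default 0.7-1.5 cycles across
#' genes), reflecting animal-to-animal variability of expressed genes in
#' inflamed tissue; reference candidates sit near the technical noise floor.
#'
#' @param n_genes Total number of genes (>= 8).
#' @param design The [study_design] (trajectory length follows its time
#'   points; amplitude defaults assume the 7-point default design).
#' @param stable_noise_sd Noise SD of the 3 stable genes (cycles).
#' @param null_noise_range Range of per-gene noise SDs spread evenly across
#'   the null genes.
#' @param spike_amplitude Peak log2 fold change of the spike gene (at the
#'   3rd time point, 4 h in the default design).
#' @param drift_amplitude Peak log2 fold change of the drifting gene (at the
#'   5th time point, 18 h in the default design).
#' @return Named list of [gene_archetype] objects.
#' @export
study_archetypes <- function(n_genes = 96L, design = study_design(),
                             stable_noise_sd = 0.25,
                             null_noise_range = c(0.7, 1.5),
                             spike_amplitude = 7.70,
                             drift_amplitude = 1.49) {
  n_genes <- as.integer(n_genes)
  if (n_genes < 8L)
    stop("need at least 8 genes for the default truth mix")
  k <- length(design$time_points_h)
  zero <- rep(0, k)
  ramp <- function(peak_idx, amplitude) {
    # piecewise-linear rise to the peak then decay toward the end
    tr <- zero
    up <- seq(0, amplitude, length.out = peak_idx)
    tr[seq_len(peak_idx)] <- up
    if (peak_idx < k)
      tr[(peak_idx + 1L):k] <- amplitude * rev(seq(0.2, 0.8,
                                                   length.out = k - peak_idx))
    tr
  }
  spike_idx <- min(3L, k)
  drift_idx <- min(5L, k)
  arks <- list(
    gene_archetype("stable_1", "stable", 22, zero, stable_noise_sd),
    gene_archetype("stable_2", "stable", 24, zero, stable_noise_sd),
    gene_archetype("stable_3", "stable", 26, zero, stable_noise_sd),
    gene_archetype("spike_1", "spike", 30, ramp(spike_idx, spike_amplitude), 0.4),
    gene_archetype("drift_1", "drift", 18, ramp(drift_idx, drift_amplitude), 0.3),
    gene_archetype("batch_1", "batch_artifact", 12, zero, 2.0),
    gene_archetype("dropout_1", "dropout", 39.8, zero, 0.5,
                   dropout_ct_threshold = 40),
    gene_archetype("dropout_2", "dropout", 39.8, zero, 0.5,
                   dropout_ct_threshold = 40)
  )
  n_null <- n_genes - length(arks)
  if (n_null > 0L) {
    sds <- seq(null_noise_range[1L], null_noise_range[2L],
               length.out = n_null)
    base <- seq(22, 32, length.out = n_null)
    nulls <- lapply(seq_len(n_null), function(i) {
      gene_archetype(sprintf("null_%02d", i), "null", base[i], zero, sds[i])
    })
    arks <- c(arks, nulls)
  }
  names(arks) <- vapply(arks, `[[`, "", "name")
  arks
}

#' Simulate a Ct matrix with known ground truth
#'
#' Generates `Ct(g, s) = baseline_ct(g) - log2_trajectory(g, time(s)) -
#' array_effect(s) + N(0, noise_sd(g))`. Cells exceeding a gene's dropout
#' threshold are recorded missing. The shared per-sample array effect is an
#' additive Ct shift common to all genes on one array (technical sample
#' quality); its default SD is 0.
#'
#' Identical `(design, archetypes, seed)` produce bit-identical tables. The
#' global RNG state is saved and restored, so simulation has no side effect
#' on the caller's random stream.
#'
#' @param design A [study_design].
#' @param archetypes List of [gene_archetype] objects (one gene each).
#' @param array_effect_sd SD (cycles) of the shared per-sample array effect.
#' @param seed Integer seed.
#' @param technical_missing Optional named integer vector (gene -> count):
#'   blanks that many single-replicate cells at interior time points of the
#'   gene, planting unexplained (technical) missing values.
#' @return A list of class `ct_simulation`: `table` (a [ct_table]) and
#'   `truth` (class `sim_truth`: per-gene archetype kinds and parameters,
#'   per-sample array effects, the seed, and any planted missing cells).
#' @examples
#' sim <- simulate_ct(study_design(), study_archetypes(12), seed = 1)
#' sim$table
#' @export
simulate_ct <- function(design, archetypes, array_effect_sd = 0, seed,
                        technical_missing = NULL) {
  stopifnot(inherits(design, "study_design"))
  if (length(archetypes) < 1L)
    stop("at least one gene archetype is required")
  k <- length(design$time_points_h)
  for (a in archetypes) {
    if (!inherits(a, "gene_archetype"))
      stop("`archetypes` must be a list of gene_archetype objects")
    if (length(a$log2_trajectory) != k)
      stop(sprintf("archetype '%s': trajectory length %d != %d time points",
                   a$name, length(a$log2_trajectory), k))
  }
  genes <- unname(vapply(archetypes, `[[`, "", "name"))
  if (anyDuplicated(genes))
    stop("duplicated gene names in archetypes")
  n_s <- length(design$sample_ids)
  tp_index <- match(design$time_h, design$time_points_h)

  withr_seed <- function(expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
  }

  withr_seed({
    array_effect <- stats::rnorm(n_s, 0, array_effect_sd)
    names(array_effect) <- design$sample_ids
    ct <- matrix(NA_real_, length(genes), n_s,
                 dimnames = list(genes, design$sample_ids))
    for (i in seq_along(archetypes)) {
      a <- archetypes[[i]]
      mu <- a$baseline_ct - a$log2_trajectory[tp_index] - array_effect
      ct[i, ] <- mu + stats::rnorm(n_s, 0, a$noise_sd)
      if (!is.na(a$dropout_ct_threshold))
        ct[i, ct[i, ] > a$dropout_ct_threshold] <- NA_real_
    }
    planted <- data.frame(gene = character(), sample = character(),
                          stringsAsFactors = FALSE)
    if (!is.null(technical_missing)) {
      interior <- design$time_points_h[-c(1L, k)]
      for (g in names(technical_missing)) {
        if (!g %in% genes)
          stop("technical_missing names an unknown gene: ", g)
        n_miss <- technical_missing[[g]]
        tps <- sample(interior, n_miss)
        for (tp in tps) {
          s_at <- which(design$time_h == tp)
          s <- s_at[sample.int(length(s_at), 1L)]
          ct[g, s] <- NA_real_
          planted <- rbind(planted, data.frame(
            gene = g, sample = design$sample_ids[s],
            stringsAsFactors = FALSE))
        }
      }
    }
    tbl <- ct_table(ct, design$time_h, validate = FALSE)
    truth <- structure(list(
      genes = data.frame(
        gene = genes,
        kind = vapply(archetypes, `[[`, "", "kind"),
        baseline_ct = vapply(archetypes, `[[`, 0, "baseline_ct"),
        noise_sd = vapply(archetypes, `[[`, 0, "noise_sd"),
        stringsAsFactors = FALSE, row.names = NULL),
      trajectories = do.call(rbind, lapply(archetypes, `[[`,
                                           "log2_trajectory")),
      array_effect = array_effect,
      planted_technical_missing = planted,
      seed = seed), class = "sim_truth")
    rownames(truth$trajectories) <- genes
    structure(list(table = tbl, truth = truth), class = "ct_simulation")
  })
}

#' @export
print.ct_simulation <- function(x, ...) {
  cat("ct_simulation (seed", x$truth$seed, ")\n")
  print(x$table)
  print(table(x$truth$genes$kind))
  invisible(x)
}

#' Write simulation ground truth as JSON
#'
#' @param truth A `sim_truth` object from [simulate_ct()].
#' @param path Output path.
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  out <- list(
    seed = truth$seed,
    genes = truth$genes,
    trajectories = as.data.frame(truth$trajectories),
    array_effect = as.list(truth$array_effect),
    planted_technical_missing = truth$planted_technical_missing)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
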