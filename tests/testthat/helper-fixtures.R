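# In-code fixtures shared across test files.

# sample ids for a design, as the package's TSV dialect expects
mk_samples <- function(time_points, replicates) {
  unlist(mapply(function(tp, n) sprintf("t%sh_r%d", format(tp, trim = TRUE),
                                        seq_len(n)),
                time_points, replicates, SIMPLIFY = FALSE))
}

# ct_table straight from a matrix (colnames encode time/replicate)
mk_ct <- function(m, validate = FALSE) ct_table(m, validate = validate)

# expr_table straight from a matrix of x = 41 - Ct values
mk_expr <- function(m, scheme = "none", provenance = NULL) {
  expr_table(m, parse_time(colnames(m)), provenance = provenance,
             scheme = scheme)
}

parse_time <- function(ids) as.numeric(sub("^t([0-9.]+)h_r[0-9]+$", "\\1", ids))

# the default 7-point / 23-sample design of the emulated study
default_samples <- function() {
  mk_samples(c(0, 1, 4, 9, 18, 27, 50), c(3, 4, 4, 3, 3, 3, 3))
}

# archetype set of n null genes with shared noise, for null simulations
null_archetypes <- function(n, noise_sd = 0.3, baseline = 25) {
  lapply(seq_len(n), function(i)
    gene_archetype(sprintf("null_%02d", i), "null", baseline,
                   rep(0, 7), noise_sd))
}

# archetypes for the artifact experiments: a drifting reference (2^1.49
# peaking at the 5th time point), one stable gene, and truth-null genes
artifact_archetypes <- function(n_null = 30, null_sd = 0.3) {
  drift_traj <- c(0, 0.37, 0.75, 1.12, 1.49, 1.19, 0.30)
  c(list(
    gene_archetype("drift_1", "drift", 18, drift_traj, 0.3),
    gene_archetype("stable_1", "stable", 22, rep(0, 7), 0.25)),
    null_archetypes(n_null, noise_sd = null_sd))
}

# 96-gene pre-analytic fixture: null genes, 10 of which carry 2 planted
# unexplained (single-replicate, interior) missing cells, plus one gene made
# biologically absent at the start of the time course
preanalytic_fixture <- function(seed = 101) {
  arks <- null_archetypes(96, noise_sd = 0.3)
  planted <- stats::setNames(rep(2L, 10L),
                             sprintf("null_%02d", 1:10))
  sim <- simulate_ct(study_design(), arks, seed = seed,
                     technical_missing = planted)
  ct <- sim$table$ct
  # biological edge absence: undetected in every replicate at t = 0 and 1 h
  edge <- grepl("^t0h_|^t1h_", colnames(ct))
  ct["null_20", edge] <- NA_real_
  list(table = ct_table(ct, validate = FALSE),
       planted_genes = names(planted), edge_gene = "null_20",
       edge_cells = colnames(ct)[edge])
}
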