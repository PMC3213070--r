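make_one_gene_ct <- function(missing_samples) {
  ids <- default_samples()
  m <- matrix(25, 1, length(ids), dimnames = list("g", ids))
  m[1, match(missing_samples, ids)] <- NA_real_
  mk_ct(m)
}

test_that("edge-of-time-course absence is biological, the rest technical", {
  # undetected in every replicate at t = 0 and 1 h, detected thereafter
  edge <- c("t0h_r1", "t0h_r2", "t0h_r3",
            "t1h_r1", "t1h_r2", "t1h_r3", "t1h_r4")
  cls <- classify_missing(make_one_gene_ct(edge))
  expect_identical(nrow(cls), 7L)
  expect_true(all(cls$class == "biological"))

  # one of three replicates at t = 9 h: technical failure
  cls <- classify_missing(make_one_gene_ct("t9h_r2"))
  expect_identical(cls$class, "technical")

  # all replicates missing at an interior time point: still unexplained
  cls <- classify_missing(make_one_gene_ct(c("t9h_r1", "t9h_r2", "t9h_r3")))
  expect_true(all(cls$class == "technical"))

  # run touching the edge plus a lone replicate elsewhere
  cls <- classify_missing(make_one_gene_ct(c("t0h_r1", "t0h_r2", "t0h_r3",
                                             "t4h_r2")))
  expect_identical(cls$class[cls$time_h == 0], rep("biological", 3L))
  expect_identical(cls$class[cls$time_h == 4], "technical")

  # absence at the END of the time course is biological too
  tail_run <- c("t27h_r1", "t27h_r2", "t27h_r3",
                "t50h_r1", "t50h_r2", "t50h_r3")
  cls <- classify_missing(make_one_gene_ct(tail_run))
  expect_true(all(cls$class == "biological"))

  # nothing missing: empty classification
  expect_identical(nrow(classify_missing(make_one_gene_ct(character()))), 0L)
})

test_that("sidecar overrides replace the automatic classification", {
  tbl <- make_one_gene_ct("t9h_r2")
  ov <- data.frame(gene = "g", sample = "t9h_r2", class = "biological",
                   stringsAsFactors = FALSE)
  cls <- classify_missing(tbl, overrides = ov)
  expect_identical(cls$class, "biological")
  imp <- impute_and_flag(tbl, cls)
  expect_identical(unname(imp$table$ct["g", "t9h_r2"]), 40)
})

test_that("imputation assigns Ct 40 to biological and time-point means to technical cells", {
  ids <- default_samples()
  m <- matrix(30, 2, length(ids), dimnames = list(c("a", "b"), ids))
  m["a", c("t0h_r1", "t0h_r2", "t0h_r3")] <- NA_real_  # biological edge
  m["b", "t9h_r1"] <- NA_real_                          # technical
  m["b", c("t9h_r2", "t9h_r3")] <- c(24, 26)
  tbl <- mk_ct(m)
  imp <- impute_and_flag(tbl)
  expect_true(all(imp$table$ct["a", c("t0h_r1", "t0h_r2", "t0h_r3")] == 40))
  expect_identical(unname(imp$table$ct["b", "t9h_r1"]), 25)
  expect_identical(unname(imp$provenance["a", "t0h_r1"]), "assigned_ct40")
  expect_identical(unname(imp$provenance["b", "t9h_r1"]), "imputed_mean")
  expect_false(anyNA(imp$table$ct))

  # a table with no missing values comes back unchanged
  full <- mk_ct(matrix(28, 1, length(ids), dimnames = list("g", ids)))
  expect_identical(impute_and_flag(full)$table$ct, full$ct)

  # interior all-replicate absence is unrecoverable by imputation
  bad <- make_one_gene_ct(c("t9h_r1", "t9h_r2", "t9h_r3"))
  expect_error(impute_and_flag(bad), "should have been filtered")
  kept <- impute_and_flag(bad, on_unrecoverable = "keep")
  expect_identical(sum(kept$provenance == "unrecoverable"), 3L)
})

test_that("filtering removes exactly the genes with >= 2 unexplained missing cells", {
  fx <- preanalytic_fixture()
  cls <- classify_missing(fx$table)
  flt <- filter_genes(fx$table, cls)
  expect_setequal(flt$removed$gene, fx$planted_genes)
  expect_identical(nrow(flt$table$ct), 86L)
  # the biologically absent gene carries 7 missing cells but is retained
  expect_true(fx$edge_gene %in% rownames(flt$table$ct))

  # a single technical missing cell is below the removal threshold
  one <- make_one_gene_ct("t9h_r2")
  expect_identical(nrow(filter_genes(one, classify_missing(one))$removed), 0L)
})

test_that("the 41 - Ct transform is the documented bijection", {
  ids <- default_samples()
  m <- matrix(rep(c(40, 25, 31.5), length.out = 23), 1, 23,
              dimnames = list("g", ids))
  ex <- ct_to_expression(mk_ct(m))
  expect_identical(ex$x[1, 1], 1)       # Ct 40 -> x = 1 (pseudocount)
  expect_identical(ex$x[1, 2], 16)      # Ct 25 -> x = 16
  expect_equal(41 - ex$x, m, ignore_attr = FALSE)   # exact round trip
  # affine reflection preserves the MAD
  expect_identical(gene_mad(ex$x[1, ]), gene_mad(m[1, ]))
  bad <- m; bad[1, 1] <- 41.5
  expect_error(ct_to_expression(mk_ct(bad, validate = FALSE)), "Ct > 41")
  miss <- m; miss[1, 1] <- NA_real_
  expect_error(ct_to_expression(mk_ct(miss)), "impute")
})

test_that("array-mean QC separates tracking from batch-artifact genes", {
  ids <- default_samples()
  set.seed(42)
  base <- matrix(rnorm(2 * 23, 25, 1), 2, 23,
                 dimnames = list(c("a", "b"), ids))
  tracker <- rbind(base, tracker = colMeans(base) + 3)
  expect_equal(qc_reference_vs_array_mean(mk_ct(tracker), "tracker"), 1)
  anti <- rbind(base, anti = 50 - colMeans(base))
  expect_equal(qc_reference_vs_array_mean(mk_ct(anti), "anti"), -1)
  flat <- rbind(base, flat = rep(20, 23))
  expect_error(qc_reference_vs_array_mean(mk_ct(flat), "flat"),
               "zero variance")

  # Monte Carlo: an independent-shift artifact gene shows |r| < 0.5 against
  # the mean of 85 null genes in at least 95% of simulations
  arks <- c(null_archetypes(85),
            list(gene_archetype("batch_1", "batch_artifact", 12,
                                rep(0, 7), 2.0)))
  hits <- vapply(1:200, function(s) {
    tbl <- simulate_ct(study_design(), arks, seed = 1000 + s)$table
    abs(qc_reference_vs_array_mean(tbl, "batch_1")) < 0.5
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("the pre-analytic pipeline is idempotent and accounts for every gene", {
  fx <- preanalytic_fixture()
  ex <- preprocess_ct(fx$table)
  expect_false(anyNA(ex$x))
  expect_true(all(ex$x > 0))
  # biological edge cells were assigned Ct 40, i.e. x = 1
  expect_true(all(ex$x[fx$edge_gene, fx$edge_cells] == 1))
  # gene accounting: retained + removed = input
  expect_setequal(c(rownames(ex$x), ex$removed$gene), rownames(fx$table$ct))
  # re-running on a table derived from the output changes nothing
  again <- preprocess_ct(ct_table(41 - ex$x, ex$time_h, validate = FALSE))
  expect_equal(again$x, ex$x, tolerance = 1e-12)
  expect_identical(nrow(again$removed), 0L)
})
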