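expr_from_groups <- function(groups, times = NULL) {
  if (is.null(times)) times <- seq(0, by = 4, length.out = length(groups))
  ids <- mk_samples(times, lengths(groups))
  mk_expr(matrix(unlist(groups), 1, length(ids), dimnames = list("g", ids)))
}

test_that("one-way ANOVA reproduces the hand-computed sums of squares", {
  # SSB = 6 (df 2), SSW = 6 (df 6) -> F = 3
  gr <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  ex <- expr_from_groups(gr)
  orc <- oracle_anova(gr)
  expect_equal(orc$F, 3)
  expect_equal(anova_per_gene(ex, "g"), orc$p, tolerance = 1e-12)
  expect_equal(anova_per_gene(ex, "g"), 0.125, tolerance = 1e-3)
})

test_that("ANOVA p agrees with the closed-form oracle on random instances", {
  set.seed(71)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    gr <- lapply(seq_len(k), function(j) rnorm(sample(2:5, 1)))
    ex <- expr_from_groups(gr)
    expect_equal(anova_per_gene(ex, "g"), oracle_anova(gr)$p,
                 tolerance = 1e-10)
  }
})

test_that("with two groups the ANOVA p equals the pooled t-test p", {
  set.seed(72)
  a <- rnorm(4); b <- rnorm(5, 1)
  ex <- expr_from_groups(list(a, b))
  expect_equal(anova_per_gene(ex, "g"),
               t.test(a, b, var.equal = TRUE)$p.value, tolerance = 1e-12)
})

test_that("null ANOVA p-values are uniform", {
  set.seed(73)
  p <- vapply(1:1000, function(i) {
    ex <- expr_from_groups(list(rnorm(3), rnorm(3), rnorm(3)))
    anova_per_gene(ex, "g")
  }, 0)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("degenerate ANOVA inputs are signalled", {
  ex <- expr_from_groups(list(c(5, 5, 5), c(5, 5, 5)))
  expect_warning(p <- anova_per_gene(ex, "g"), "undefined")
  expect_true(is.nan(p))
  # zero noise but different means: maximally significant
  ex2 <- expr_from_groups(list(c(5, 5, 5), c(7, 7, 7)))
  expect_identical(anova_per_gene(ex2, "g"), 0)
  one_rep <- mk_expr(matrix(1:2, 1, 2,
                            dimnames = list("g", mk_samples(c(0, 4),
                                                            c(1, 1)))))
  expect_error(anova_per_gene(one_rep, "g"), "2 samples")
})

test_that("Kruskal-Wallis matches the exact rank formula", {
  gr <- list(c(1, 2), c(3, 4), c(5, 6))
  orc <- oracle_kw(gr)
  expect_equal(orc$H, 32 / 7, tolerance = 1e-12)
  ex <- expr_from_groups(gr)
  expect_equal(kruskal_wallis_per_gene(ex, "g"), orc$p, tolerance = 1e-12)
  expect_equal(kruskal_wallis_per_gene(ex, "g"), 0.102, tolerance = 1e-2)
  # tie-corrected random instances
  set.seed(74)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    gr <- lapply(seq_len(k), function(j)
      sample(1:4, sample(3:6, 1), replace = TRUE))   # plenty of ties
    ex <- expr_from_groups(gr)
    expect_equal(kruskal_wallis_per_gene(ex, "g"), oracle_kw(gr)$p,
                 tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis is invariant under monotone transforms and flags all-tied input", {
  set.seed(75)
  gr <- list(rnorm(4, 0), rnorm(4, 1), rnorm(4, 2))
  ex1 <- expr_from_groups(gr)
  ex2 <- expr_from_groups(lapply(gr, function(g) exp(g) + 1))
  expect_equal(kruskal_wallis_per_gene(ex1, "g"),
               kruskal_wallis_per_gene(ex2, "g"), tolerance = 1e-12)
  tied <- expr_from_groups(list(c(2, 2, 2), c(2, 2, 2)))
  expect_warning(h <- kruskal_wallis_per_gene(tied, "g"), "tied")
  expect_true(is.nan(h))
})

test_that("BH adjustment implements the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(76)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_identical(order(q[order(p)]), seq_along(p))  # monotone in ranks
  }
})

test_that("the t-test targets the time point of greatest change", {
  # planted spike: the maximum must be found at 4 h
  arks <- list(gene_archetype("sp", "spike", 30, c(0, 0, 7.7, 0, 0, 0, 0), 0),
               gene_archetype("st", "stable", 24, rep(0, 7), 0))
  ex <- preprocess_ct(simulate_ct(study_design(), arks, seed = 1)$table)
  expect_error(ttest_at_max(ex, "sp"), "degenerate")  # zero variance groups
  res_st <- ttest_at_max(ex, "st")
  expect_identical(res_st$max_fc, 1)                 # all-flat gene
  expect_true(is.na(res_st$p))

  # hand-computed pooled t: sp^2 = 0.04, n = 3 + 3 -> t = 12.25
  ids <- mk_samples(c(0, 4), c(3, 3))
  m <- matrix(c(10.0, 10.2, 9.8, 12.0, 12.2, 11.8), 1, 6,
              dimnames = list("g", ids))
  res <- ttest_at_max(mk_expr(m), "g")
  expect_identical(res$max_fc_time, 4)
  t_hand <- 2 / (0.2 * sqrt(2 / 3))
  expect_equal(res$p, 2 * pt(t_hand, df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$p, 0.00026, tolerance = 0.02)
})

test_that("greatest change means greatest in either direction, ties to the earlier point", {
  ids <- mk_samples(c(0, 4, 9), c(3, 3, 3))
  # down 2-fold at 4 h beats up 1.5-fold at 9 h
  m <- matrix(c(10, 10.1, 9.9, 9, 9.1, 8.9, 10.585, 10.685, 10.485), 1, 9,
              dimnames = list("g", ids))
  res <- ttest_at_max(mk_expr(m), "g")
  expect_identical(res$max_fc_time, 4)
  expect_equal(res$max_fc, 2, tolerance = 1e-12)
  # exact tie in |log2 FC| resolves to the earlier time point
  m2 <- matrix(c(10, 10, 10.3, 9, 9, 9.3, 11, 11, 11.3), 1, 9,
               dimnames = list("g", ids))
  expect_identical(ttest_at_max(mk_expr(m2), "g")$max_fc_time, 4)
})

test_that("regulated calling applies both thresholds and one BH family per condition", {
  res <- data.frame(gene = c("a", "b", "c"),
                    anova_p_bh = c(0.001, 0.049, 0.051),
                    max_fc = c(1.49, 3.0, 3.0))
  expect_identical(call_regulated(res), "b")
  sim <- simulate_ct(study_design(), study_archetypes(24), seed = 12)
  tests <- gene_tests(preprocess_ct(sim$table))
  expect_equal(tests$anova_p_bh, bh_adjust(tests$anova_p), tolerance = 1e-12)
  expect_true(all(tests$anova_p_bh >= tests$anova_p, na.rm = TRUE))
  expect_true(all(tests$max_fc >= 1, na.rm = TRUE))
  expect_setequal(call_regulated(tests), tests$gene[tests$regulated])
})

test_that("grand mean per time point is linear in a single spike", {
  ids <- default_samples()
  m <- matrix(10, 85, 23, dimnames = list(sprintf("g%02d", 1:85), ids))
  ex <- mk_expr(m)
  expect_equal(unname(overall_mean_by_time(ex)), rep(10, 7))
  m2 <- m
  m2["g01", parse_time(ids) == 4] <- 10 + 7.7
  om <- overall_mean_by_time(mk_expr(m2))
  expect_equal(unname(om[as.character(4)]) - 10, 7.7 / 85, tolerance = 1e-12)
  expect_equal(unname(om[as.character(0)]), 10)
})

test_that("regulated sets agree between no normalization and a stable reference on noise-free data", {
  arks <- list(
    gene_archetype("sp", "spike", 30, c(0, 0, 7.7, 0, 0, 0, 0), 0),
    gene_archetype("ref", "stable", 22, rep(0, 7), 0),
    gene_archetype("fl", "stable", 24, rep(0, 7), 0))
  ex <- preprocess_ct(simulate_ct(study_design(), arks, seed = 1)$table)
  t_none <- gene_tests(ex, ttest = FALSE)
  t_ref <- gene_tests(normalize_expression(ex, norm_scheme("single", "ref")),
                      ttest = FALSE)
  expect_setequal(call_regulated(t_none), call_regulated(t_ref))
})
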