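test_that("plug-in effect-size formula: identities and the printed anchor", {
  expect_equal(effect_size_mode_formula(0, 0, 1, 1), 0)
  expect_equal(effect_size_mode_formula(1, 0, 1, 1), 1)
  # printed group moments 273.7 +/- 35.1 vs 266.1 +/- 32.3 -> mode ~0.22
  v <- effect_size_mode_formula(273.7, 266.1, 35.1, 32.3)
  expect_equal(v, 0.225, tolerance = 0.002)
  expect_lt(abs(v - 0.22), 0.01)
  expect_error(effect_size_mode_formula(1, 0, 0, 1), "positive")
})

test_that("a permuted copy of the same sample is n.s. with P ~ 50%", {
  set.seed(1)
  y <- rnorm(30, 10, 2)
  cmp <- best_compare(y, sample(y), n_mcmc = 20000, seed = 2)
  expect_lt(cmp$prob_diff_pct, 60)
  expect_identical(cmp$tier, "n.s.")
})

test_that("a 3-SD standardized difference is highly significant", {
  g <- gen_group_scores(group_spec(3, 1, 25, 0, 1, 25, seed = 3))
  cmp <- best_compare(g$group1, g$group2, n_mcmc = 20000, seed = 4)
  expect_gt(cmp$prob_diff_pct, 99)
  expect_identical(cmp$tier, "highly significant")
  expect_gt(cmp$es_mode, 0)
  expect_equal(sign(cmp$es_mode), sign(cmp$diff_mean))
})

test_that("comparisons are seed-deterministic", {
  g <- gen_group_scores(group_spec(1, 1, 15, 0.5, 1, 15, seed = 5))
  a <- best_compare(g$group1, g$group2, n_mcmc = 5000, seed = 6)
  b <- best_compare(g$group1, g$group2, n_mcmc = 5000, seed = 6)
  expect_identical(a$prob_diff_pct, b$prob_diff_pct)
  expect_identical(a$es_mode, b$es_mode)
  expect_identical(a$draws, b$draws)
})

test_that("posterior effect-size mode converges to the plug-in formula for large n", {
  # scaled down from very large n for runtime; documented in the vignette
  g <- gen_group_scores(group_spec(0.5, 1, 4000, 0, 1, 4000, seed = 7))
  cmp <- best_compare(g$group1, g$group2, n_mcmc = 8000, burn = 500, seed = 8)
  plug <- effect_size_mode_formula(mean(g$group1), mean(g$group2),
                                   sd(g$group1), sd(g$group2))
  expect_lt(abs(cmp$es_mode - plug), 0.02)
})

test_that("tier thresholds follow the 80 / 90 rules", {
  expect_identical(tier_from_prob(79.9), "n.s.")
  expect_identical(tier_from_prob(80.1), "significant")
  expect_identical(tier_from_prob(90.1), "highly significant")
  expect_true(all(vapply(list(best_compare(rnorm(10), rnorm(10), 2000, seed = 1)),
                         function(x) x$prob_diff_pct >= 50 && x$prob_diff_pct <= 100,
                         logical(1))))
})

test_that("null calibration of the 80% criterion is reported, not hard-failed", {
  set.seed(9)
  flags <- vapply(1:20, function(i) {
    cmp <- best_compare(rnorm(20), rnorm(20), n_mcmc = 2000, burn = 500,
                        seed = 100 + i)
    cmp$tier != "n.s."
  }, logical(1))
  rate <- mean(flags)
  # the probability-of-difference is ~Uniform(50, 100) under the null, so the
  # nominal flag rate of the 80% rule is ~40%; just bound and report it
  expect_gte(rate, 0); expect_lte(rate, 1)
  message(sprintf("null-calibration flag rate of the 80%% rule: %.2f (nominal ~0.4)", rate))
})

test_that("JZS one-way ANOVA Bayes factor behaves under null and large effects", {
  set.seed(10)
  bfs_null <- vapply(1:20, function(i)
    bf_anova_oneway(list(rnorm(40), rnorm(40)))$bf10, numeric(1))
  expect_lt(median(bfs_null), 1)
  g <- gen_group_scores(group_spec(2, 1, 25, 0, 1, 25, seed = 11))
  big <- bf_anova_oneway(list(g$group1, g$group2))
  expect_gt(big$bf10, 100)
  expect_identical(big$verdict, "highest")
  # verdict consistent with the returned bf10 at the 3 / 10 / 100 thresholds
  for (sep in c(0, 0.6, 1.0, 2)) {
    gg <- gen_group_scores(group_spec(sep, 1, 20, 0, 1, 20, seed = 12))
    r <- bf_anova_oneway(list(gg$group1, gg$group2))
    want <- if (r$bf10 > 100) "highest" else if (r$bf10 > 10) "highly significant"
            else if (r$bf10 > 3) "significant" else "none"
    expect_identical(r$verdict, want)
  }
  expect_error(bf_anova_oneway(list(rnorm(10))), ">= 2 groups")
  expect_error(bf_anova_oneway("x"), ">= 2 groups")
  # three-group case runs and yields a finite positive BF
  expect_gt(bf_anova_oneway(list(rnorm(15), rnorm(15), rnorm(15, 2)))$bf10, 0)
})

test_that("compare_table reproduces the printed tier pattern on moment-matched data", {
  rows <- tab1_anchor_rows()[c("t1", "t3", "t6")]
  tabs <- lapply(names(rows), function(id) {
    g <- anchor_groups(rows[[id]], seed = 21)
    data.frame(measure = id,
               group = rep(c("control", "carrier"), each = 25),
               value = c(g$group1, g$group2))
  })
  tab <- compare_table(do.call(rbind, tabs), n_mcmc = 20000, seed = 13)
  expect_identical(tab$tier[tab$measure == "t1"], "n.s.")                 # 78.3%
  expect_identical(tab$tier[tab$measure == "t3"], "highly significant")   # 94.8%
  expect_identical(tab$tier[tab$measure == "t6"], "highly significant")   # 97.4%
  # shuffled row order gives identical per-measure results
  shuf <- do.call(rbind, tabs); shuf <- shuf[sample(nrow(shuf)), ]
  tab2 <- compare_table(shuf, n_mcmc = 20000, seed = 13)
  expect_equal(as.data.frame(tab), as.data.frame(tab2))
})

test_that("covariate residualization: empty covariates equal the plain comparison", {
  g <- anchor_groups(tab1_anchor_rows()$t3, seed = 22)
  df <- data.frame(measure = "m", group = rep(c("a", "b"), each = 25),
                   value = c(g$group1, g$group2),
                   age = runif(50, 20, 80))
  plain <- compare_table(df, n_mcmc = 5000, seed = 14)
  nocov <- compare_table(df, covariates = NULL, n_mcmc = 5000, seed = 14)
  expect_equal(as.data.frame(plain), as.data.frame(nocov))
  withcov <- compare_table(df, covariates = "age", n_mcmc = 5000, seed = 14)
  expect_s3_class(withcov, "comparison_table")
  expect_error(compare_table(df, covariates = "sex", n_mcmc = 2000), "sex")
  one_group <- data.frame(measure = "m", group = "a", value = rnorm(5))
  expect_error(expect_warning(compare_table(one_group, n_mcmc = 2000),
                              "exactly 2 groups"))
})
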