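test_that("Welch t-test matches the closed-form oracle", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(3, 4, 5, 6, 7)
  res <- welch_ttest(a, b)
  # closed form: se = sqrt(s1^2/n1 + s2^2/n2), Welch-Satterthwaite df
  se <- sqrt(var(a) / 5 + var(b) / 5)
  t_oracle <- (mean(a) - mean(b)) / se
  df_oracle <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$statistic, -2, tolerance = 1e-12)
  expect_equal(res$df, df_oracle, tolerance = 1e-12)
  expect_equal(res$df, 8)
  expect_equal(res$p.value, 2 * pt(t_oracle, df_oracle), tolerance = 1e-12)
  expect_equal(res$p.value, 0.08052, tolerance = 1e-4)

  same <- welch_ttest(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(welch_ttest(rep(1, 5), rep(1, 5)),
               class = "gaitlf_error_degenerate")
})

test_that("a 3-sigma group gap is detected essentially always", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    welch_ttest(rnorm(30), rnorm(30, mean = 3))$p.value < 0.001
  }, TRUE)
  expect_gte(mean(hits), 0.98)
})

test_that("ANCOVA isolates an injected group effect in the noise-free limit", {
  tb <- simulate_metrics_cohort(n_per_group = 20, seed = 3)
  set.seed(3)
  # pure group signal (vanishing residual noise keeps the F test defined)
  tb$mean_FM <- 0.5 + 0.5 * (tb$group == "PSP") + rnorm(40, 0, 1e-4)
  a <- suppressWarnings(ancova(tb, "mean_FM"))
  td <- tidy(a)
  expect_lt(td$p.value[td$term == "group"], 1e-10)
  # the group term carries essentially all the variance
  expect_gt(td$sumsq[td$term == "group"],
            1e6 * max(td$sumsq[td$term != "group"]))
})

test_that("a dependent that is a pure function of age is fully explained", {
  tb <- simulate_metrics_cohort(n_per_group = 20, seed = 4)
  set.seed(4)
  tb$max_LE_L <- 0.01 * tb$age + rnorm(40, 0, 1e-4)
  a <- suppressWarnings(ancova(tb, "max_LE_L"))
  expect_gt(glance(a)$r.squared, 1 - 1e-5)
  td <- tidy(a)
  expect_lt(td$p.value[td$term == "age"], 1e-10)
})

test_that("covariate-free ANCOVA reduces to one-way ANOVA (F = t^2)", {
  set.seed(11)
  tb <- tibble::tibble(
    group = factor(rep(c("Control", "PSP"), each = 25)),
    mean_FM = rnorm(50, mean = rep(c(0.6, 0.7), each = 25), sd = 0.1))
  a <- suppressWarnings(ancova(tb, "mean_FM", covariates = character()))
  f_group <- tidy(a)$statistic[tidy(a)$term == "group"]
  t_pooled <- t.test(mean_FM ~ group, data = tb, var.equal = TRUE)$statistic
  expect_equal(f_group, unname(t_pooled)^2, tolerance = 1e-9)
})

test_that("ANCOVA attaches assumption diagnostics without gating", {
  tb <- simulate_metrics_cohort(n_per_group = 25, seed = 6)
  a <- suppressWarnings(ancova(tb, "max_LE_S"))
  gl <- glance(a)
  expect_true(is.finite(gl$ad_p.value))
  expect_true(is.finite(gl$levene_p.value))
  expect_true(all(tidy(a)$p.value >= 0 & tidy(a)$p.value <= 1))
})

test_that("rank-deficient designs fail loudly", {
  tb <- simulate_metrics_cohort(n_per_group = 10, seed = 7)
  tb$dup <- tb$age
  expect_error(suppressWarnings(ancova(tb, "mean_FM",
                                       covariates = c("age", "dup"))),
               class = "gaitlf_error_validation")
})

test_that("post-hoc regression recovers constructed slopes in reporting units", {
  tb <- simulate_metrics_cohort(n_per_group = 15, seed = 8)
  tb$mean_FM <- 0.01 * tb$age            # 0.1 per decade exactly
  r <- posthoc_regression(tb, "mean_FM", "age")
  expect_equal(nrow(r), 2)
  expect_equal(r$slope_scaled, c(0.1, 0.1), tolerance = 1e-9)
  expect_equal(r$r.squared, c(1, 1), tolerance = 1e-9)
  expect_true(all(r$p.value < 1e-10))
  expect_identical(unique(r$scale_units), "per decade")

  # cadence slope 0.046/step -> 0.23 per 5 steps/min, recovered under noise
  set.seed(9)
  tb$max_LE_S <- 2 + 0.046 * tb$cadence + rnorm(nrow(tb), 0, 0.1)
  rc <- posthoc_regression(tb, "max_LE_S", "cadence")
  # noise sd 0.1, cadence sd ~4-5, n = 15: slope SE (scaled) ~ 0.03-0.04
  expect_lt(max(abs(rc$slope_scaled - 0.23)), 0.12)
  expect_equal(rc$slope_scaled, rc$slope * 5)
})

test_that("null post-hoc regressions stay null", {
  ps <- vapply(1:60, function(s) {
    tb <- simulate_metrics_cohort(n_per_group = 15, effect = FALSE,
                                  seed = 100 + s)
    min(posthoc_regression(tb, "mean_FM", "age")$p.value)
  }, 1)
  # two groups tested per replicate; Sidak-ish null rate
  expect_gte(mean(ps > 0.05), 0.8)
})

test_that("degenerate post-hoc inputs raise typed errors", {
  tb <- simulate_metrics_cohort(n_per_group = 5, seed = 10)
  tb$age <- 70
  expect_error(posthoc_regression(tb, "mean_FM", "age"),
               class = "gaitlf_error_degenerate")
})

test_that("Spearman correlation honours monotone transforms and ranks", {
  tb <- simulate_metrics_cohort(n_per_group = 12, seed = 11)
  psp <- tb$group == "PSP"
  tb$mean_FM[psp] <- exp(tb$psprs[psp] / 10)        # monotone increasing
  expect_equal(spearman_corr(tb, "mean_FM", "psprs")$rho, 1)
  tb$max_LE_L[psp] <- -as.numeric(tb$psprs[psp])    # monotone decreasing
  expect_equal(spearman_corr(tb, "max_LE_L", "psprs")$rho, -1)
  tb$psprs_gm[psp] <- 9L
  expect_error(spearman_corr(tb, "mean_FM", "psprs_gm"),
               class = "gaitlf_error_degenerate")
})

test_that("independent metric/severity pairs rarely show large rho", {
  # null sd of rho at n = 40 is ~0.16, so P(|rho| < 0.32) ~ 0.95; assert a
  # 2.3-sigma lower bound under 200 Monte-Carlo draws
  hits <- vapply(1:200, function(s) {
    tb <- simulate_metrics_cohort(n_per_group = 40, seed = 200 + s)
    abs(spearman_corr(tb, "max_LE_S", "psprs")$rho) < 0.32
  }, TRUE)
  expect_gte(mean(hits), 0.92)
})

test_that("every statistic is invariant to row order", {
  tb <- simulate_metrics_cohort(n_per_group = 20, seed = 12)
  set.seed(13)
  perm <- tb[sample(nrow(tb)), ]
  expect_equal(tidy(suppressWarnings(ancova(perm, "mean_FM"))),
               tidy(suppressWarnings(ancova(tb, "mean_FM"))),
               tolerance = 1e-12)
  expect_equal(demographics_tests(perm), demographics_tests(tb),
               tolerance = 1e-12)
  expect_equal(spearman_corr(perm, "mean_FM", "psprs"),
               spearman_corr(tb, "mean_FM", "psprs"), tolerance = 1e-12)
})
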