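#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom,
#' returned as a one-row tibble.
#'
#' @param a,b Numeric samples, each of length at least 2.
#' @return Tibble with `estimate_a`, `estimate_b`, `statistic`, `df`,
#'   `p.value`.
#' @export
welch_ttest <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop_validation("each sample needs at least 2 finite observations.")
  }
  if (var(a) == 0 && var(b) == 0) {
    stop_degenerate("both samples have zero variance; the Welch statistic is undefined.")
  }
  tt <- t.test(a, b, var.equal = FALSE)
  tibble(estimate_a = mean(a), estimate_b = mean(b),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p.value = tt$p.value)
}

#' Welch tests on the demographic variables
#'
#' Runs [welch_ttest()] per demographic variable between the two groups.
#'
#' @param table Cohort table with `group` and the demographic columns.
#' @param variables Columns to test (defaults to age, height, mass,
#'   cadence, intersected with what is present).
#' @return Tibble, one row per variable.
#' @export
demographics_tests <- function(table,
                               variables = c("age", "height_m", "mass_kg",
                                             "cadence")) {
  variables <- intersect(variables, names(table))
  purrr::map_dfr(variables, function(v) {
    res <- welch_ttest(table[[v]][table$group == "Control"],
                       table[[v]][table$group == "PSP"])
    dplyr::bind_cols(tibble(variable = v), res)
  })
}

#' ANCOVA on a stability metric with covariates and assumption checks
#'
#' Fits `dependent ~ group + covariates` by ordinary least squares and
#' reports Type-II F tests per term (order-invariant for this design).
#' Assumptions are checked, never silently acted on: Anderson-Darling
#' normality of the residuals and Levene's test (median-centred) for
#' homogeneity of the dependent's variance across groups, both attached as
#' diagnostics with a warning when violated.
#'
#' @param table Cohort table; `group` must have exactly two levels and
#'   `sex`, when used, is treated as a factor.
#' @param dependent Name of the metric column (e.g. `"mean_FM"`).
#' @param covariates Character vector of covariate columns
#'   (default `c("sex", "age", "cadence")`).
#' @return A `gait_ancova` object with [tidy()] (per-term F table) and
#'   [glance()] (model fit plus assumption diagnostics) methods.
#' @export
ancova <- function(table, dependent, covariates = c("sex", "age", "cadence")) {
  table <- as.data.frame(table)
  need <- c(dependent, "group", covariates)
  missing <- setdiff(need, names(table))
  if (length(missing) > 0L) {
    stop_validation(sprintf("table lacks column(s): %s",
                            paste(missing, collapse = ", ")))
  }
  if (anyNA(table[[dependent]])) {
    stop_validation(sprintf("missing values in dependent `%s`.", dependent))
  }
  table$group <- droplevels(factor(table$group))
  if (nlevels(table$group) != 2L) {
    stop_validation("`group` must have exactly two levels.")
  }
  if ("sex" %in% covariates) {
    table$sex <- factor(table$sex)
  }
  form <- reformulate(c("group", covariates), response = dependent)
  fit <- lm(form, data = table)
  al <- alias(fit)
  if (!is.null(al$Complete)) {
    stop_validation(sprintf("rank-deficient design; aliased term(s): %s",
                            paste(rownames(al$Complete), collapse = ", ")))
  }
  an <- car::Anova(fit, type = 2)
  terms_tbl <- tibble(
    term = rownames(an),
    sumsq = an[["Sum Sq"]],
    df = an[["Df"]],
    statistic = an[["F value"]],
    p.value = an[["Pr(>F)"]]
  )
  terms_tbl <- terms_tbl[terms_tbl$term != "Residuals", ]
  res <- residuals(fit)
  ad <- tryCatch(nortest::ad.test(res),
                 error = function(e) list(statistic = NA_real_,
                                          p.value = NA_real_))
  lev <- car::leveneTest(table[[dependent]] ~ table$group, center = median)
  ad_p <- unname(ad$p.value)
  lev_p <- lev[["Pr(>F)"]][1]
  if (is.finite(ad_p) && ad_p < 0.05) {
    warn(sprintf("ANCOVA on `%s`: residual normality questionable (Anderson-Darling p = %.3g).",
                 dependent, ad_p))
  }
  if (is.finite(lev_p) && lev_p < 0.05) {
    warn(sprintf("ANCOVA on `%s`: variance homogeneity questionable (Levene p = %.3g).",
                 dependent, lev_p))
  }
  structure(list(
    dependent = dependent,
    covariates = covariates,
    fit = fit,
    terms = terms_tbl,
    normality = list(statistic = unname(ad$statistic), p.value = ad_p),
    levene = list(statistic = lev[["F value"]][1], p.value = lev_p)
  ), class = "gait_ancova")
}

#' @export
print.gait_ancova <- function(x, ...) {
  cat(sprintf("<gait_ancova> %s ~ group + %s\n", x$dependent,
              paste(x$covariates, collapse = " + ")))
  print(x$terms)
  invisible(x)
}

#' @export
tidy.gait_ancova <- function(x, ...) {
  x$terms
}

#' @export
glance.gait_ancova <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    dependent = x$dependent,
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    df.residual = x$fit$df.residual,
    ad_statistic = x$normality$statistic,
    ad_p.value = x$normality$p.value,
    levene_statistic = x$levene$statistic,
    levene_p.value = x$levene$p.value
  )
}

#' Post-hoc per-group linear regression
#'
#' Ordinary least squares of a stability metric on one predictor, fitted
#' separately within each group. Slopes are additionally rescaled to the
#' conventional clinical reporting units: per decade of age, per 5 steps/min
#' of cadence (exact multiplications by 10 and 5).
#'
#' @param table Cohort table.
#' @param dependent Metric column name.
#' @param predictor `"age"` or `"cadence"`.
#' @return Tibble, one row per group: raw `slope`, `slope_scaled`,
#'   `scale_units`, `intercept`, `r.squared`, `p.value`, `n`.
#' @export
posthoc_regression <- function(table, dependent, predictor = c("age", "cadence")) {
  predictor <- match.arg(predictor)
  scale <- if (predictor == "age") 10 else 5
  units <- if (predictor == "age") "per decade" else "per 5 steps/min"
  table <- as.data.frame(table)
  purrr::map_dfr(levels(factor(table$group)), function(g) {
    sub <- table[table$group == g, c(dependent, predictor)]
    sub <- sub[complete.cases(sub), ]
    if (nrow(sub) < 3L) {
      stop_insufficient(sprintf("group `%s` has fewer than 3 usable rows.", g))
    }
    if (sd(sub[[predictor]]) == 0) {
      stop_degenerate(sprintf(
        "`%s` is constant within group `%s`; regression undefined.",
        predictor, g))
    }
    fit <- lm(reformulate(predictor, response = dependent), data = sub)
    s <- summary(fit)
    tibble(group = g, dependent = dependent, predictor = predictor,
           slope = unname(coef(fit)[2]),
           slope_scaled = unname(coef(fit)[2]) * scale,
           scale_units = units,
           intercept = unname(coef(fit)[1]),
           r.squared = s$r.squared,
           p.value = s$coefficients[2, 4],
           n = nrow(sub))
  })
}

#' Spearman correlation of a metric with disease severity
#'
#' Rank correlation (tie-corrected) between a stability metric and a
#' clinical severity score within the PSP group. The p-value uses the
#' t-approximation for n > 10 and the exact permutation distribution
#' otherwise (falling back to the approximation when ties make the exact
#' distribution unavailable).
#'
#' @param table Cohort table containing PSP rows with severity scores.
#' @param metric Metric column name.
#' @param severity `"psprs"` or `"psprs_gm"`.
#' @return One-row tibble with `rho`, `p.value`, `n`.
#' @export
spearman_corr <- function(table, metric, severity = c("psprs", "psprs_gm")) {
  severity <- match.arg(severity)
  sub <- table[table$group == "PSP", c(metric, severity)]
  sub <- sub[complete.cases(sub), ]
  n <- nrow(sub)
  if (n < 5L) {
    stop_validation("need at least 5 paired PSP observations.")
  }
  if (sd(sub[[severity]]) == 0) {
    stop_degenerate("severity scores are all tied; rank correlation undefined.")
  }
  x <- sub[[metric]]
  y <- sub[[severity]]
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = n <= 10))
  tibble(metric = metric, severity = severity,
         rho = unname(ct$estimate), p.value = ct$p.value, n = n)
}
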