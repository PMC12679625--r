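test_that("oscillator labels carry the closed-form ground truth", {
  s <- simulate_linear_oscillator(0.1, 2 * pi, 1, 10, 120, seed = 1)
  gt <- ground_truth(s)
  expect_equal(gt$fm_abs, exp(-0.2 * pi))
  expect_equal(gt$max_le_l, -0.2 * pi)
  s0 <- simulate_linear_oscillator(0, 2 * pi, 1, 10, 120, seed = 1)
  expect_equal(ground_truth(s0)$fm_abs, 1)
  expect_equal(ground_truth(s0)$max_le_l, 0)
  expect_error(simulate_linear_oscillator(-0.1, 2 * pi, 1, 10, 120),
               class = "gaitlf_error_validation")
  expect_error(simulate_linear_oscillator(0.1, 2 * pi, 1, 10, rate = 1),
               class = "gaitlf_error_validation")
})

test_that("seeds control noise but not labels", {
  a <- simulate_linear_oscillator(0.1, 2 * pi, 1, 10, 120, seed = 1,
                                  noise_sd = 0.01, kick_cv = 0.2)
  b <- simulate_linear_oscillator(0.1, 2 * pi, 1, 10, 120, seed = 2,
                                  noise_sd = 0.01, kick_cv = 0.2)
  a2 <- simulate_linear_oscillator(0.1, 2 * pi, 1, 10, 120, seed = 1,
                                   noise_sd = 0.01, kick_cv = 0.2)
  expect_false(isTRUE(all.equal(a$value, b$value)))
  expect_identical(a$value, a2$value)
  expect_equal(ground_truth(a), ground_truth(b))
})

test_that("the marker generator produces a pipeline-consistent capture", {
  g <- simulate_marker_gait(zeta = 0.1, cadence = 50, noise_sd = 0, seed = 4,
                            n_trials = 2)
  expect_length(g$trials, 2)
  mts <- g$trials[[1]]
  expect_setequal(marker_names(mts),
                  c("RHEE", "LHEE", "RPSI", "LPSI", "RASI", "LASI"))
  expect_equal(g$label$T, 2.4)
  # CoM - CoP equals the underlying sway exactly when noise-free
  y <- relative_ml_signal(com_surrogate(mts), cop_surrogate(mts))
  expect_lt(sd(y$value), 0.1)
  expect_gt(sd(y$value), 0.001)
  # 8 strides/trial with a 2+2 trim leaves 4 analyzable strides per trial
  ev <- detect_gait_events(mts)
  tr <- trim_boundary_strides(y, ev, n_trim = 2)
  expect_length(stride_anchors(tr), 5)   # 5 strikes bound 4 strides
  expect_error(simulate_marker_gait(zeta = 0.1, cadence = 50,
                                    strides_per_trial = 4),
               class = "gaitlf_error_validation")
})

test_that("cohort simulation is seed-deterministic and spec-shaped", {
  spec <- cohort_spec(n_per_group = 4, seed = 99)
  co <- simulate_cohort(spec, markers = FALSE)
  expect_equal(nrow(co$participants), 8)
  expect_equal(as.character(unique(co$participants$group)),
               c("Control", "PSP"))
  expect_true(all(is.na(co$participants$psprs[co$participants$group == "Control"])))
  expect_true(all(!is.na(co$participants$psprs[co$participants$group == "PSP"])))
  expect_true(all(co$participants$zeta > 0 & co$participants$zeta < 1))
  expect_equal(co$participants$fm_abs_true,
               exp(-co$participants$zeta * co$participants$omega *
                     co$participants$stride_time_s))
  co2 <- simulate_cohort(spec, markers = FALSE)
  expect_identical(co$participants, co2$participants)
  # empty cohort is allowed
  empty <- simulate_cohort(cohort_spec(n_per_group = 0), markers = FALSE)
  expect_equal(nrow(empty$participants), 0)
})

test_that("cohort demographics follow the configured distributions", {
  co <- simulate_cohort(cohort_spec(n_per_group = 400, seed = 5),
                        markers = FALSE)$participants
  ctrl <- co[co$group == "Control", ]
  psp <- co[co$group == "PSP", ]
  # the [50, 95] age truncation lifts the Control mean by ~0.8 years
  expect_lt(abs(mean(ctrl$age) - 64), 2.5)
  expect_lt(abs(mean(psp$age) - 71), 2.5)
  expect_lt(abs(mean(ctrl$cadence_target) - 55), 1)
  expect_lt(abs(mean(psp$cadence_target) - 50), 1)
  # Control damping degrades with age; PSP damping is age-independent
  expect_lt(cor(ctrl$age, ctrl$zeta), -0.2)
  expect_lt(abs(cor(psp$age, psp$zeta)), 0.2)
  # severity scores independent of the dynamics
  expect_lt(abs(cor(psp$psprs, psp$zeta)), 0.2)
})

test_that("the metrics-level cohort reproduces the configured group gaps", {
  tb <- do.call(rbind, lapply(1:20, function(s)
    simulate_metrics_cohort(n_per_group = 30, seed = s)))
  gap_fm <- mean(tb$mean_FM[tb$group == "PSP"]) -
    mean(tb$mean_FM[tb$group == "Control"])
  expect_lt(abs(gap_fm - 0.11), 0.02)
  expect_lt(abs(sd(tb$mean_FM[tb$group == "Control"]) - 0.16), 0.02)
  null <- simulate_metrics_cohort(n_per_group = 200, effect = FALSE, seed = 1)
  gap0 <- mean(null$mean_FM[null$group == "PSP"]) -
    mean(null$mean_FM[null$group == "Control"])
  expect_lt(abs(gap0), 0.05)
})

test_that("Lorenz integration stays on the attractor and is reproducible", {
  lx <- simulate_lorenz(rate = 100, duration = 30, seed = 1)
  expect_equal(nrow(lx), 3000)
  expect_lt(max(abs(lx$value)), 25)
  lx2 <- simulate_lorenz(rate = 100, duration = 30, seed = 1)
  expect_identical(lx$value, lx2$value)
  # subcritical rho: the origin is a stable fixed point
  fp <- simulate_lorenz(rho = 0.5, rate = 100, duration = 30, seed = 1)
  expect_lt(abs(tail(fp$value, 1)), 1e-3)
})

test_that("the analytic Floquet oracle handles canonical cases", {
  z <- analytic_floquet_oracle(matrix(0, 2, 2), T = 1)
  expect_equal(Mod(z$fm), c(1, 1))
  expect_equal(z$le, c(0, 0))
  d <- analytic_floquet_oracle(diag(c(-1, -2)), T = 1)
  expect_equal(sort(Mod(d$fm)), sort(exp(c(-2, -1))), tolerance = 1e-6)
  expect_equal(sort(d$le), c(-2, -1))
  o <- analytic_floquet_oracle(gaitlf:::oscillator_matrix(0.1, 2 * pi), T = 1)
  expect_equal(unique(round(Mod(o$fm), 4)), 0.5335)
  expect_equal(max(o$le), -0.6283, tolerance = 1e-4)
})
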