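# The damped linear oscillator is the canonical fixture: its Floquet
# multipliers and Lyapunov exponents are known in closed form and through
# the independent matrix-exponential oracle.

osc_monodromy <- function(zeta, omega = 2 * pi, T = 1, n_strides = 60,
                          rate = 120, seed = 1, filter = FALSE, ...) {
  sim <- simulate_linear_oscillator(zeta = zeta, omega = omega, T = T,
                                    n_strides = n_strides, rate = rate,
                                    seed = seed, ...)
  if (filter) {
    sim <- lowpass_filter(mean_normalize(sim))
  }
  emb <- delay_embed(differentiate(sim), tau = 1, n = 0, stride_time = T)
  estimate_monodromy(emb)
}

test_that("estimated monodromy matches the matrix-exponential oracle", {
  A <- gaitlf:::oscillator_matrix(0.1, 2 * pi)
  oracle <- analytic_floquet_oracle(A, T = 1)
  m <- osc_monodromy(0.1)
  expect_equal(sort(Mod(m$fm)), sort(Mod(oracle$fm)), tolerance = 0.05)
  expect_equal(m$mean_abs_fm, exp(-0.2 * pi), tolerance = 0.05 * exp(-0.2 * pi))
  expect_equal(m$max_le_l, -0.2 * pi, tolerance = 0.05 * 0.2 * pi)
  expect_equal(max(oracle$le), -0.2 * pi, tolerance = 1e-10)
  # element-wise agreement of Phi with e^{AT}
  expect_lt(max(abs(m$phi - oracle$phi)), 1e-3)
})

test_that("the neutrally stable oscillator sits on the unit circle", {
  m <- osc_monodromy(0, kick_cv = 0.2)
  expect_equal(m$mean_abs_fm, 1, tolerance = 0.02)
  expect_equal(m$max_le_l, 0, tolerance = 0.02)
})

test_that("stability metrics are strictly monotone in damping", {
  ms <- lapply(c(0.05, 0.1, 0.2), osc_monodromy)
  fm <- vapply(ms, function(m) m$mean_abs_fm, 1)
  le <- vapply(ms, function(m) m$max_le_l, 1)
  expect_true(all(diff(fm) < 0))
  expect_true(all(diff(le) < 0))
})

test_that("Floquet exponents are branch-consistent with the multipliers", {
  m <- osc_monodromy(0.1)
  expect_equal(exp(m$exponents * m$stride_time), m$fm, tolerance = 1e-9)
})

test_that("an identity monodromy gives unit multipliers and zero exponents", {
  r <- floquet_from_phi(diag(4), stride_time = 1.2)
  expect_equal(Mod(r$fm), rep(1, 4))
  expect_equal(Re(r$exponents), rep(0, 4))
  expect_equal(summarize_fm(r), 1)
})

test_that("summarize_fm averages eigenvalue magnitudes", {
  # spectrum {0.5, 0.5 +/- 0.2i}: mean of {0.5, 0.53852, 0.53852}
  phi <- matrix(0, 3, 3)
  phi[1, 1] <- 0.5
  phi[2:3, 2:3] <- matrix(c(0.5, -0.2, 0.2, 0.5), 2)
  r <- floquet_from_phi(phi, stride_time = 1)
  expect_equal(summarize_fm(r), (0.5 + 2 * sqrt(0.5^2 + 0.2^2)) / 3,
               tolerance = 1e-12)
  expect_equal(summarize_fm(r), 0.5257, tolerance = 1e-4)
})

test_that("observation noise shifts max LE_L only modestly in the median", {
  # noise at 5% of signal amplitude, both arms through the pipeline's
  # 10 Hz low-pass treatment before differentiation
  shifts <- vapply(1:20, function(s) {
    clean <- osc_monodromy(0.1, seed = s, kick_cv = 0.2, target_rms = 0.03,
                           filter = TRUE)
    noisy <- osc_monodromy(0.1, seed = s, kick_cv = 0.2, target_rms = 0.03,
                           noise_sd = 0.05 * 0.03, filter = TRUE)
    abs(noisy$max_le_l - clean$max_le_l)
  }, 1)
  expect_lt(median(shifts), 0.1)
})

test_that("insufficient or degenerate section data raises typed errors", {
  sim <- simulate_linear_oscillator(0.1, 2 * pi, 1, 5, 120, seed = 1)
  emb <- delay_embed(differentiate(sim), 1, 0, stride_time = 1)
  expect_error(estimate_monodromy(emb, n_phases = 1, min_pairs = 10),
               class = "gaitlf_error_insufficient_data")
  expect_error(estimate_monodromy(emb, stride_time = -1),
               class = "gaitlf_error_validation")
})

test_that("stability assessment applies the inclusive FM/LE criteria", {
  mk <- function(fm_max, le_max) {
    list(max_abs_fm = fm_max, max_le_l = le_max, fm = fm_max)
  }
  a <- assess_stability(mk(0.9, -0.2))
  expect_true(a$stable_fm)
  expect_true(a$stable_le)
  expect_identical(a$label, "stable")
  b <- assess_stability(mk(1.1, -0.1))
  expect_false(b$stable_fm)
  # boundary cases are inclusive
  c_ <- assess_stability(mk(1.0, 0.0))
  expect_true(c_$stable_fm)
  expect_true(c_$stable_le)
})

test_that("tidy/glance expose the spectrum and summary", {
  m <- osc_monodromy(0.1)
  td <- tidy(m)
  expect_true(all(c("modulus", "exponent_re", "exponent_re_per_stride") %in%
                    names(td)))
  expect_equal(nrow(td), m$rank)
  gl <- glance(m)
  expect_equal(gl$mean_abs_fm, m$mean_abs_fm)
  expect_equal(gl$max_le_l_per_stride, m$max_le_l * m$stride_time)
})
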