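test_that("differentiation matches the analytic derivative of a sinusoid", {
  rate <- 120
  t <- (0:1199) / rate
  Y <- make_traj(sin(2 * pi * t), stage = "filtered")
  ph <- differentiate(Y)
  truth <- 2 * pi * cos(2 * pi * t)
  mid <- 2:1199
  expect_lt(max(abs(ph$ydot[mid] - truth[mid])) / max(abs(truth)), 1e-3)
})

test_that("differentiation is exact on constants and ramps", {
  expect_equal(differentiate(make_traj(rep(0.3, 50)))$ydot, rep(0, 50))
  ramp <- make_traj(0.5 * (0:49) / 120)
  expect_equal(differentiate(ramp)$ydot, rep(0.5, 50), tolerance = 1e-12)
  expect_error(differentiate(make_traj(c(1, 2))),
               class = "gaitlf_error_validation")
})

test_that("the embedding delay lands on the physically meaningful scale", {
  # noisy oscillation with period 120 samples: delay within [P/8, P/2]
  set.seed(5)
  x <- scalar_traj(sin(2 * pi * (0:2399) / 120) + rnorm(2400, 0, 0.05),
                   rate = 120)
  tau <- optimal_delay(x)
  expect_gte(tau, 15)
  expect_lte(tau, 60)
  # white noise: immediate loss of information
  set.seed(6)
  w <- scalar_traj(rnorm(3000), rate = 120)
  expect_lte(optimal_delay(w), 3)
  expect_error(optimal_delay(scalar_traj(rep(1, 500), rate = 120)),
               class = "gaitlf_error_validation")
})

test_that("AMI is non-negative and the oracle curve matches a direct computation", {
  set.seed(9)
  x <- rnorm(400)
  got <- average_mutual_information(x, max_lag = 5, bins = 4)
  # independent brute-force oracle with the same binning contract
  L <- length(x)
  b <- ceiling(rank(x, ties.method = "first") * 4 / L)
  for (k in 1:5) {
    n <- L - k
    tab <- table(factor(b[1:n], 1:4), factor(b[(k + 1):L], 1:4))
    p <- tab / n
    pi_ <- rowSums(p); pj_ <- colSums(p)
    mi <- sum(p[p > 0] * log(p[p > 0] / outer(pi_, pj_)[p > 0]))
    expect_equal(got$ami[k], mi, tolerance = 1e-12)
  }
  expect_true(all(got$ami > -1e-12))
})

test_that("FNN selects a planar embedding for a sinusoid and unfolds Lorenz", {
  s <- make_traj(sin(2 * pi * (0:2399) / 120), stage = "filtered")
  ps <- differentiate(s)
  expect_identical(optimal_dimension(ps, tau = 30, theiler = 120), 0L)

  lx <- simulate_lorenz(rate = 100, duration = 60, seed = 2)
  n <- optimal_dimension(differentiate(lx), tau = 15, theiler = 75)
  expect_gte(2 * (n + 1), 3)   # total dimension at least 3
  expect_gte(n, 1)

  short <- differentiate(make_traj(rnorm(50), stage = "filtered"))
  expect_error(optimal_dimension(short, tau = 10, max_n = 8),
               class = "gaitlf_error_validation")
})

test_that("delay embedding has the right shape, identity case and masking", {
  ph <- differentiate(make_traj(rnorm(200), stage = "filtered"))
  e0 <- delay_embed(ph, tau = 5, n = 0)
  expect_equal(dim(e0$states), c(2L, 200L))
  expect_equal(e0$states[1, ], ph$y)
  expect_equal(e0$states[2, ], ph$ydot)

  e2 <- delay_embed(ph, tau = 5, n = 2)
  expect_equal(dim(e2$states), c(6L, 190L))      # L - n*tau columns
  expect_equal(e2$states[3, 1], ph$y[6])         # m(t + tau) block
  expect_error(delay_embed(ph, tau = 100, n = 2),
               class = "gaitlf_error_validation")

  # junction masking: columns spanning a boundary are flagged
  attr(ph, "boundaries") <- c(100L)
  em <- delay_embed(ph, tau = 5, n = 2)
  expect_true(all(em$mask[91:100]))
  expect_false(any(em$mask[c(1:90, 101:190)]))
})

test_that("embedded states of a periodic signal recur after one period", {
  t <- (0:2399) / 120
  ph <- differentiate(make_traj(sin(2 * pi * t), stage = "filtered"))
  emb <- delay_embed(ph, tau = 30, n = 1)
  P <- 120
  cols <- 200:400
  gap <- emb$states[, cols + P] - emb$states[, cols]
  expect_lt(max(abs(gap)), 1e-6)
})
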