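test_that("CoM surrogate is the pelvis-marker mean along M/L", {
  # one frame, pelvis M/L at {0.01, 0.02, 0.03, 0.04}: mean 0.025
  dat <- tibble::tibble(time = 0)
  ml <- c(RASI = 0.01, LASI = 0.02, RPSI = 0.03, LPSI = 0.04,
          RHEE = -0.1, LHEE = 0.1)
  for (nm in names(ml)) {
    dat[[paste0(nm, "_x")]] <- ml[[nm]]
    dat[[paste0(nm, "_y")]] <- 0
    dat[[paste0(nm, "_z")]] <- 0
  }
  mts <- marker_set(dat, rate = 120)
  expect_equal(com_surrogate(mts)$value, 0.025)
  expect_equal(cop_surrogate(mts)$value, 0)    # heels at -0.1/+0.1
})

test_that("surrogates recover the generator's CoM/CoP traces exactly", {
  com <- 0.02 * sin(2 * pi * (0:599) / 120) + 0.001 * (0:599) / 120
  mts <- make_marker_fixture(n = 600, com_ml = com)
  expect_equal(com_surrogate(mts)$value, com, tolerance = 1e-12)
  expect_equal(cop_surrogate(mts)$value, rep(0, 600), tolerance = 1e-12)
  y <- relative_ml_signal(com_surrogate(mts), cop_surrogate(mts))
  expect_equal(y$value, com, tolerance = 1e-12)
  expect_identical(signal_stage(y), "raw")
})

test_that("surrogates ignore A/P and vertical translations", {
  mts <- make_marker_fixture(n = 400)
  shifted <- as.data.frame(mts)
  for (lab in marker_names(mts)) {
    shifted[[paste0(lab, "_y")]] <- shifted[[paste0(lab, "_y")]] + 3.7
    shifted[[paste0(lab, "_z")]] <- shifted[[paste0(lab, "_z")]] - 0.4
  }
  mts2 <- marker_set(shifted, rate = 120)
  expect_equal(com_surrogate(mts2)$value, com_surrogate(mts)$value)
  expect_equal(cop_surrogate(mts2)$value, cop_surrogate(mts)$value)
})

test_that("relative_ml_signal validates alignment and subtracts", {
  a <- scalar_traj(rep(0.025, 10), rate = 120)
  b <- scalar_traj(rep(0, 10), rate = 120)
  expect_equal(relative_ml_signal(a, b)$value, rep(0.025, 10))
  expect_equal(relative_ml_signal(a, a)$value, rep(0, 10))
  expect_error(relative_ml_signal(a, scalar_traj(rep(0, 9), rate = 120)),
               class = "gaitlf_error_validation")
  expect_error(relative_ml_signal(a, scalar_traj(rep(0, 10), rate = 100)),
               class = "gaitlf_error_validation")
})

test_that("mean_normalize zeroes the mean and advances the stage", {
  y <- make_traj(rep(0.025, 100))
  out <- mean_normalize(y)
  expect_equal(out$value, rep(0, 100))
  expect_identical(signal_stage(out), "normalized")
  y2 <- make_traj(c(-1, 1))
  expect_equal(mean_normalize(y2)$value, c(-1, 1))
  set.seed(1)
  y3 <- make_traj(rnorm(500, mean = 3))
  expect_lt(abs(mean(mean_normalize(y3)$value)), 1e-12)
})

test_that("stitching concatenates, records junctions and shifts anchors", {
  trials <- lapply(1:5, function(i) {
    tr <- make_traj(rnorm(400), stage = "normalized")
    attr(tr, "anchors") <- c(50L, 250L)
    tr
  })
  out <- stitch_trials(trials)
  expect_equal(nrow(out), 2000)
  expect_equal(trial_boundaries(out), c(400L, 800L, 1200L, 1600L))
  expect_equal(stride_anchors(out),
               as.integer(c(50, 250) + rep((0:4) * 400, each = 2)))
  expect_identical(signal_stage(out), "stitched")
  # single trial: identity values, no boundaries
  one <- stitch_trials(trials[1])
  expect_equal(one$value, trials[[1]]$value)
  expect_length(trial_boundaries(one), 0)
  # sample conservation under permutation of trials
  out2 <- stitch_trials(trials[c(3, 1, 5, 2, 4)])
  expect_equal(sort(out2$value), sort(out$value))
  expect_error(stitch_trials(list()), class = "gaitlf_error_validation")
  bad <- trials
  attr(bad[[2]], "rate") <- 100
  expect_error(stitch_trials(bad), class = "gaitlf_error_validation")
})

test_that("zero-phase Butterworth keeps the passband and kills the stopband", {
  rate <- 120
  t <- (0:4799) / rate
  pass <- make_traj(sin(2 * pi * 1 * t), stage = "stitched")
  out <- lowpass_filter(pass)
  mid <- 600:4200
  amp <- max(abs(out$value[mid]))
  expect_gt(amp, 0.99)
  expect_lt(amp, 1.01)
  # zero phase: cross-correlation peak at zero lag
  cc <- ccf(out$value[mid], pass$value[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  stop_ <- make_traj(sin(2 * pi * 30 * t), stage = "stitched")
  expect_lt(max(abs(lowpass_filter(stop_)$value[mid])), 0.05)

  zero <- make_traj(rep(0, 1000), stage = "stitched")
  expect_equal(lowpass_filter(zero)$value, rep(0, 1000))

  expect_error(lowpass_filter(pass, cutoff = 60),
               class = "gaitlf_error_validation")
})

test_that("filtering is linear", {
  set.seed(42)
  x <- make_traj(rnorm(2000), stage = "stitched")
  z <- make_traj(rnorm(2000), stage = "stitched")
  comb <- make_traj(2 * x$value - 0.5 * z$value, stage = "stitched")
  lhs <- lowpass_filter(comb)$value
  rhs <- 2 * lowpass_filter(x)$value - 0.5 * lowpass_filter(z)$value
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("the pipeline stage ordering is enforced", {
  raw <- make_traj(rnorm(500), stage = "raw")
  expect_error(stitch_trials(list(raw)), class = "gaitlf_error_validation")
  expect_error(lowpass_filter(raw), class = "gaitlf_error_validation")
  norm <- mean_normalize(raw)
  st <- stitch_trials(list(norm, mean_normalize(make_traj(rnorm(500)))))
  fl <- lowpass_filter(st)
  expect_identical(vapply(list(raw, norm, st, fl), signal_stage, ""),
                   c("raw", "normalized", "stitched", "filtered"))
})
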