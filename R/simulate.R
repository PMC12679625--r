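#' Simulate a kicked damped linear oscillator with closed-form ground truth
#'
#' Integrates xddot = -omega^2 x - 2 zeta omega xdot + u(t) exactly
#' (per-sample matrix-exponential propagation with zero-order-hold input),
#' where u(t) is a smooth half-sine force pulse delivered once per stride
#' period T — the continuous push that sustains the medio-lateral sway of
#' the centre of mass, analogous to each step's ground-reaction impulse.
#' Because the forcing enters additively, the one-period propagator of the
#' deviation dynamics is exp(A T) regardless of the pulse shape, so the
#' closed-form labels are exact: |FM| = exp(-zeta omega T) (a
#' complex-conjugate multiplier pair) and max LE_L = -zeta omega.
#'
#' With the default `kick_cv = 0` the pulses are identical and the orbit is
#' noise-free: the transient approach to the limit cycle supplies the
#' stride-to-stride deviations the monodromy estimator measures, and the
#' recovery is exact up to finite differencing. A positive `kick_cv` adds
#' per-stride pulse-amplitude variability (process noise: realistic
#' stride-to-stride sway variation, and the required excitation for the
#' neutrally stable zeta = 0 orbit, which has no decaying transient);
#' `noise_sd` adds seeded Gaussian observation noise on top.
#'
#' @param zeta Damping ratio in \[0, 1).
#' @param omega Undamped natural frequency (rad/s).
#' @param T Stride (kick) period in seconds.
#' @param n_strides Number of strides to simulate.
#' @param rate Sampling rate in Hz (must exceed omega/pi).
#' @param noise_sd Observation noise SD in metres (default 0).
#' @param seed Integer seed; identical seeds give identical output.
#' @param kick_velocity Mean per-stride velocity impulse (m/s), delivered
#'   as a half-sine force pulse.
#' @param kick_cv Coefficient of variation of the pulse amplitude; `0`
#'   gives a noise-free periodic orbit (useful as a limit-cycle fixture).
#' @param pulse_s Pulse duration in seconds (default 0.2, the scale of a
#'   step's lateral push).
#' @param target_rms Rescale the position trace to this RMS amplitude in
#'   metres (`NULL` to keep the natural scale); rescaling is linear and does
#'   not change the stability labels.
#' @return A [scalar_traj()] with stride anchors at the kick samples and a
#'   `ground_truth` attribute (zeta, omega, T, fm_abs, max_le_l).
#' @export
simulate_linear_oscillator <- function(zeta, omega, T, n_strides, rate,
                                       noise_sd = 0, seed = 1,
                                       kick_velocity = 0.1, kick_cv = 0,
                                       pulse_s = 0.2, target_rms = NULL) {
  if (!is_scalar_number(zeta) || zeta < 0 || zeta >= 1) {
    stop_validation("`zeta` must lie in [0, 1).")
  }
  if (rate <= omega / pi) {
    stop_validation("`rate` must exceed omega/pi (sampling criterion).")
  }
  A <- oscillator_matrix(zeta, omega)
  h <- 1 / rate
  E <- pracma::expm(A * h)
  # exact zero-order-hold input matrix: integral of e^{As} B over one sample
  F_in <- solve(A, (E - diag(2)) %*% c(0, 1))
  T_samp <- round(T * rate)
  n_samples <- n_strides * T_samp + 1L
  anchors <- seq(1L, by = T_samp, length.out = n_strides)
  # half-sine force pulse with unit velocity impulse
  L_pulse <- max(2L, min(round(pulse_s * rate), T_samp - 1L))
  shape <- sin(pi * (seq_len(L_pulse) - 0.5) / L_pulse)
  shape <- shape / (sum(shape) * h)          # integral of u dt = 1
  withr::with_seed(seed, {
    amps <- kick_velocity * (1 + kick_cv * rnorm(n_strides))
    u <- numeric(n_samples)
    for (k in seq_len(n_strides)) {
      idx <- anchors[k] + seq_len(L_pulse) - 1L
      idx <- idx[idx <= n_samples]
      u[idx] <- u[idx] + amps[k] * shape[seq_along(idx)]
    }
    x <- matrix(0, nrow = 2, ncol = n_samples)
    state <- c(0, 0)
    for (i in seq_len(n_samples)) {
      x[, i] <- state
      state <- as.numeric(E %*% state + F_in * u[i])
    }
    value <- x[1, ]
    if (!is.null(target_rms)) {
      rms <- sqrt(mean(value^2))
      if (rms > 0) value <- value * (target_rms / rms)
    }
    if (noise_sd > 0) {
      value <- value + rnorm(n_samples, sd = noise_sd)
    }
  })
  out <- scalar_traj(value, rate = rate, anchors = anchors)
  attr(out, "ground_truth") <- list(
    zeta = zeta, omega = omega, T = T,
    fm_abs = exp(-zeta * omega * T),
    max_le_l = -zeta * omega)
  out
}

#' @rdname simulate_linear_oscillator
#' @param x A trajectory returned by a simulator.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

#' Simulate marker-level overground walking trials
#'
#' Emulates short (~10 m) walkway captures with the six-marker set the
#' medio-lateral analysis needs. The M/L centre-of-mass sway is a kicked
#' damped oscillator (one kick per stride at left heel strike) whose damped
#' period equals the stride period implied by `cadence`; the four pelvis
#' markers are that sway plus fixed symmetric offsets, so their mean
#' recovers it exactly. The heels sit at constant symmetric M/L offsets
#' (their mean, the CoP surrogate, is zero) and advance antero-posteriorly
#' in alternating steps, so the heel-relative-to-pelvis A/P signal peaks
#' exactly at the generated heel strikes and coordinate-based event
#' detection recovers the cadence. Observation noise is added to every
#' marker coordinate.
#'
#' @param zeta Damping ratio of the sway dynamics.
#' @param cadence Steps per minute; the stride period is `120/cadence` s.
#' @param omega Natural frequency; default places the damped period at one
#'   stride, `2*pi/(T*sqrt(1-zeta^2))`.
#' @param n_trials Number of trials (default 5).
#' @param strides_per_trial Strides per trial (default 8, so a 2+2 stride
#'   trim leaves 4 analyzable strides per trial).
#' @param rate Sampling rate in Hz (default 120).
#' @param noise_sd Marker observation noise SD in metres (default 0.002,
#'   typical optical-capture error).
#' @param seed Integer seed.
#' @param stride_length A/P advance per stride in metres (default 1.2).
#' @param sway_rms Target RMS of the M/L sway in metres (default 0.025).
#' @param kick_cv Stride-to-stride kick variability (default 0.2).
#' @return List with `trials` (list of [marker_set()]) and `label`
#'   (closed-form ground truth: zeta, omega, T, cadence, fm_abs, max_le_l).
#' @export
simulate_marker_gait <- function(zeta, cadence, omega = NULL, n_trials = 5,
                                 strides_per_trial = 8, rate = 120,
                                 noise_sd = 0.002, seed = 1,
                                 stride_length = 1.2, sway_rms = 0.025,
                                 kick_cv = 0.2) {
  T <- 120 / cadence
  omega <- omega %||% (2 * pi / (T * sqrt(1 - zeta^2)))
  n_trim_default <- 2L
  if (strides_per_trial < 2L * n_trim_default + 1L) {
    stop_validation(sprintf(
      "strides_per_trial = %d leaves nothing after trimming %d strides per end.",
      strides_per_trial, n_trim_default))
  }
  t0 <- 0.3 * T
  duration <- t0 + strides_per_trial * T + 0.25 * T
  n_frames <- round(duration * rate)
  time <- (seq_len(n_frames) - 1) / rate
  speed <- stride_length / T
  pelvis_ml_off <- c(RASI = 0.115, LASI = -0.115, RPSI = 0.095, LPSI = -0.095)
  heel_ml_off <- c(RHEE = 0.10, LHEE = -0.10)

  # heel A/P: stance hold then smooth swing advance, landing at each strike
  heel_ap <- function(strike0) {
    u <- (time - strike0) / T
    k <- floor(u)
    ph <- u - k
    ramp <- ifelse(ph < 0.6, 0, {
      s <- (ph - 0.6) / 0.4
      s * s * (3 - 2 * s)
    })
    stride_length * (k + ramp)
  }

  label <- list(zeta = zeta, omega = omega, T = T, cadence = cadence,
                fm_abs = exp(-zeta * omega * T), max_le_l = -zeta * omega)
  # one common amplitude scale per participant, taken from the noiseless
  # reference orbit: per-trial rescaling would randomize the limit-cycle
  # amplitude across trials and corrupt the pooled section statistics
  ref <- simulate_linear_oscillator(
    zeta = zeta, omega = omega, T = T,
    n_strides = strides_per_trial + 1L, rate = rate,
    noise_sd = 0, seed = 1, kick_cv = 0)
  scale_ml <- sway_rms / sqrt(mean(ref$value^2))
  trials <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    sway <- simulate_linear_oscillator(
      zeta = zeta, omega = omega, T = T,
      n_strides = strides_per_trial + 1L, rate = rate,
      noise_sd = 0, seed = seed * 1000L + tr,
      kick_cv = kick_cv)
    com_ml <- sway$value * scale_ml
    # align kicks with the left strikes at t0 + k T
    shift <- round(t0 * rate)
    com_ml <- c(rep(com_ml[1], shift), com_ml)[seq_len(n_frames)]
    pelvis_ap <- speed * time
    l_ap <- heel_ap(t0)
    r_ap <- heel_ap(t0 + 0.5 * T) - stride_length / 2
    dat <- tibble(time = time)
    add_marker <- function(dat, name, ml, ap, vert) {
      dat[[paste0(name, "_x")]] <- ml
      dat[[paste0(name, "_y")]] <- ap
      dat[[paste0(name, "_z")]] <- vert
      dat
    }
    pelvis_v <- 0.95 + 0.01 * sin(2 * pi * time / (T / 2))
    for (nm in names(pelvis_ml_off)) {
      dat <- add_marker(dat, nm, com_ml + pelvis_ml_off[[nm]],
                        pelvis_ap + ifelse(grepl("ASI", nm), 0.12, -0.12),
                        pelvis_v)
    }
    dat <- add_marker(dat, "RHEE", rep(heel_ml_off[["RHEE"]], n_frames),
                      r_ap, 0.02 + 0 * time)
    dat <- add_marker(dat, "LHEE", rep(heel_ml_off[["LHEE"]], n_frames),
                      l_ap, 0.02 + 0 * time)
    if (noise_sd > 0) {
      coord_cols <- setdiff(names(dat), "time")
      noise <- withr::with_seed(seed * 1000L + tr + 500L, {
        matrix(rnorm(n_frames * length(coord_cols), sd = noise_sd),
               nrow = n_frames)
      })
      dat[coord_cols] <- as_tibble(as.matrix(dat[coord_cols]) + noise,
                                   .name_repair = ~coord_cols)
    }
    trials[[tr]] <- marker_set(dat, rate = rate)
  }
  list(trials = trials, label = label)
}

#' Cohort specification for the synthetic gait study
#'
#' Defaults mirror the demographic and gait structure of a two-group
#' overground walking study of healthy older adults (Control) and patients
#' with progressive supranuclear palsy (PSP): 120 Hz capture, 5 trials of a
#' 10 m walkway (~8 strides each, ~20 analyzable after trimming two strides
#' per end), Control cadence 55 +/- 4 vs PSP 50 +/- 5 steps/min, ages
#' 64 +/- 10 vs 71 +/- 7 years. Group damping ratios are chosen so the
#' closed-form multiplier magnitudes exp(-zeta omega T) centre near 0.68
#' (Control) and 0.79 (PSP); Control damping degrades with age while PSP
#' damping is age-independent, and PSP severity scores are drawn
#' independently of the dynamics.
#'
#' @param n_per_group Participants per group (default 30).
#' @param rate Sampling rate in Hz.
#' @param n_trials,strides_per_trial Trial structure.
#' @param zeta Named list of per-group `c(mean, sd)` damping ratios.
#' @param cadence,age Named lists of per-group `c(mean, sd)`.
#' @param sex_prob_f Named vector of female proportions per group.
#' @param noise_sd Marker observation noise SD (m).
#' @param age_zeta_slope Control-group damping loss per year of age.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 30, rate = 120, n_trials = 5,
                        strides_per_trial = 8,
                        zeta = list(Control = c(mean = 0.061, sd = 0.02),
                                    PSP = c(mean = 0.0375, sd = 0.012)),
                        cadence = list(Control = c(mean = 55, sd = 4),
                                       PSP = c(mean = 50, sd = 5)),
                        age = list(Control = c(mean = 64, sd = 10),
                                   PSP = c(mean = 71, sd = 7)),
                        sex_prob_f = c(Control = 18 / 33, PSP = 21 / 40),
                        noise_sd = 0.002,
                        age_zeta_slope = -0.0012,
                        seed = 1) {
  structure(list(n_per_group = n_per_group, rate = rate, n_trials = n_trials,
                 strides_per_trial = strides_per_trial, zeta = zeta,
                 cadence = cadence, age = age, sex_prob_f = sex_prob_f,
                 noise_sd = noise_sd, age_zeta_slope = age_zeta_slope,
                 seed = seed),
            class = "cohort_spec")
}

draw_truncated <- function(n, mean, sd, lower, upper) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

#' Simulate a marker-level cohort
#'
#' Draws per-participant demographics and sway dynamics from a
#' [cohort_spec()] and (optionally) generates the full marker trials for
#' each participant with [simulate_marker_gait()]. All draws are pure
#' functions of the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param markers Generate marker trials (`TRUE`) or only the participant
#'   table with ground-truth labels (`FALSE`).
#' @return A `gait_cohort` list: `participants` tibble (id, group,
#'   demographics, severity scores, true zeta/omega/T and closed-form
#'   labels) and, when requested, `trials` (list of per-participant trial
#'   lists, same order).
#' @export
simulate_cohort <- function(spec = cohort_spec(), markers = TRUE) {
  n <- spec$n_per_group
  if (n == 0L) {
    empty <- tibble(id = character(), group = factor(levels = c("Control", "PSP")),
                    age = numeric(), sex = factor(levels = c("F", "M")),
                    height_m = numeric(), mass_kg = numeric(),
                    cadence_target = numeric(), zeta = numeric(),
                    omega = numeric(), stride_time_s = numeric(),
                    fm_abs_true = numeric(), max_le_l_true = numeric(),
                    psprs = integer(), psprs_gm = integer())
    return(structure(list(participants = empty,
                          trials = if (markers) list() else NULL,
                          spec = spec),
                     class = "gait_cohort"))
  }
  participants <- withr::with_seed(spec$seed, {
    rows <- lapply(c("Control", "PSP"), function(g) {
      ages <- draw_truncated(n, spec$age[[g]][["mean"]], spec$age[[g]][["sd"]],
                             50, 95)
      cad <- draw_truncated(n, spec$cadence[[g]][["mean"]],
                            spec$cadence[[g]][["sd"]], 30, 70)
      zmean <- spec$zeta[[g]][["mean"]]
      zsd <- spec$zeta[[g]][["sd"]]
      if (g == "Control") {
        zmean_i <- zmean + spec$age_zeta_slope *
          (ages - spec$age[[g]][["mean"]])
        z <- vapply(zmean_i, function(mu)
          draw_truncated(1, mu, zsd, 0.005, 0.4), numeric(1))
      } else {
        z <- draw_truncated(n, zmean, zsd, 0.005, 0.4)
      }
      Tg <- 120 / cad
      omg <- 2 * pi / (Tg * sqrt(1 - z^2))
      tibble(
        id = sprintf("%s%02d", ifelse(g == "Control", "C", "P"), seq_len(n)),
        group = factor(g, levels = c("Control", "PSP")),
        age = round(ages, 1),
        sex = factor(ifelse(runif(n) < spec$sex_prob_f[[g]], "F", "M"),
                     levels = c("F", "M")),
        height_m = round(draw_truncated(n, 1.7, 0.09, 1.45, 1.95), 2),
        mass_kg = round(draw_truncated(n, 77, 15, 45, 120), 1),
        cadence_target = cad,
        zeta = z, omega = omg, stride_time_s = Tg,
        fm_abs_true = exp(-z * omg * Tg),
        max_le_l_true = -z * omg,
        psprs = if (g == "PSP") {
          as.integer(pmin(pmax(round(rnorm(n, 35, 12)), 12), 58))
        } else NA_integer_,
        psprs_gm = if (g == "PSP") {
          as.integer(pmin(pmax(round(rnorm(n, 10, 4)), 2), 16))
        } else NA_integer_
      )
    })
    dplyr::bind_rows(rows)
  })
  trials <- NULL
  if (markers) {
    trials <- lapply(seq_len(nrow(participants)), function(i) {
      p <- participants[i, ]
      simulate_marker_gait(
        zeta = p$zeta, cadence = p$cadence_target, omega = p$omega,
        n_trials = spec$n_trials, strides_per_trial = spec$strides_per_trial,
        rate = spec$rate, noise_sd = spec$noise_sd,
        seed = spec$seed * 10000L + i)$trials
    })
  }
  structure(list(participants = participants, trials = trials, spec = spec),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d participants (%s)%s\n",
              nrow(x$participants),
              paste(table(x$participants$group), collapse = " + "),
              if (is.null(x$trials)) " [table only]" else " with marker trials"))
  invisible(x)
}

#' Simulate a metrics-level cohort table
#'
#' Draws the per-participant stability metrics directly from group
#' distributions, bypassing the marker pipeline. This is the fast input for
#' exercising the statistical layer (power and null calibration): group
#' means and spreads default to the magnitudes observed in the PSP study
#' this package models (mean |FM| 0.68 vs 0.79 with within-group SD 0.16;
#' max LE_L -0.3 vs -0.17; max LE_S 2.58 vs 2.6), with the same demographic
#' structure as [cohort_spec()]. Setting `effect = FALSE` removes every
#' group gap in the metrics (the null configuration) while keeping the
#' demographic differences.
#'
#' @param n_per_group Participants per group.
#' @param fm_mean,fm_sd Group means (named) and common SD of mean |FM|.
#' @param le_l_mean,le_l_sd Group means and SDs of max LE_L (1/s).
#' @param le_s_mean,le_s_sd Group means and SDs of max LE_S (1/s).
#' @param effect `FALSE` collapses all metric distributions onto the
#'   Control values.
#' @param seed Integer seed.
#' @return A tibble with one row per participant: demographics, cadence,
#'   `mean_FM`, `max_LE_L`, `max_LE_S`, severity scores.
#' @export
simulate_metrics_cohort <- function(n_per_group = 30,
                                    fm_mean = c(Control = 0.68, PSP = 0.79),
                                    fm_sd = 0.16,
                                    le_l_mean = c(Control = -0.3, PSP = -0.17),
                                    le_l_sd = c(Control = 0.29, PSP = 0.18),
                                    le_s_mean = c(Control = 2.58, PSP = 2.6),
                                    le_s_sd = c(Control = 0.31, PSP = 0.44),
                                    effect = TRUE, seed = 1) {
  spec <- cohort_spec(n_per_group = n_per_group, seed = seed)
  base <- simulate_cohort(spec, markers = FALSE)$participants
  withr::with_seed(seed + 1L, {
    g <- as.character(base$group)
    pick <- function(v, grp) if (effect) v[[grp]] else v[["Control"]]
    base$mean_FM <- vapply(g, function(grp)
      rnorm(1, pick(fm_mean, grp), fm_sd), numeric(1))
    base$max_LE_L <- vapply(g, function(grp)
      rnorm(1, pick(le_l_mean, grp), pick(le_l_sd, grp)), numeric(1))
    base$max_LE_S <- vapply(g, function(grp)
      rnorm(1, pick(le_s_mean, grp), pick(le_s_sd, grp)), numeric(1))
  })
  base$cadence <- base$cadence_target
  base[, c("id", "group", "age", "sex", "height_m", "mass_kg", "cadence",
           "mean_FM", "max_LE_L", "max_LE_S", "psprs", "psprs_gm")]
}

#' Simulate the Lorenz system's x-coordinate
#'
#' Fixed-step RK4 integration (step at most 0.01 s) of the Lorenz equations
#' with a seeded jitter on the initial condition; the first `transient`
#' seconds are discarded and the x-coordinate is returned resampled at
#' `rate`. The canonical parameters give a chaotic benchmark whose largest
#' Lyapunov exponent (about 0.906 1/s) is known from the Benettin oracle.
#'
#' @param sigma,rho,beta Lorenz parameters.
#' @param rate Output sampling rate in Hz.
#' @param duration Retained duration in seconds.
#' @param transient Discarded settle-in time (default 10 s).
#' @param seed Seed for the initial-condition jitter.
#' @return A [scalar_traj()] of the x-coordinate.
#' @export
simulate_lorenz <- function(sigma = 10, rho = 28, beta = 8 / 3,
                            rate = 100, duration = 200, transient = 10,
                            seed = 1) {
  substeps <- max(1L, ceiling((1 / rate) / 0.01))
  dt <- (1 / rate) / substeps
  f <- function(x) lorenz_field(x, sigma, rho, beta)
  x <- withr::with_seed(seed, c(1, 1, 20) + rnorm(3, sd = 0.1))
  n_trans <- round(transient / dt)
  for (i in seq_len(n_trans)) {
    x <- rk4_step(x, dt, f)
  }
  n_out <- round(duration * rate)
  out <- numeric(n_out)
  for (i in seq_len(n_out)) {
    for (s in seq_len(substeps)) {
      x <- rk4_step(x, dt, f)
    }
    out[i] <- x[1]
  }
  scalar_traj(out, rate = rate, stage = "raw")
}
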