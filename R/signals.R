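#' Scalar gait trajectories
#'
#' A `scalar_traj` is a tibble with `time` (s) and `value` (m) columns plus
#' attributes: the sampling `rate` (Hz), the processing `stage`
#' (`raw -> normalized -> stitched -> filtered`), `boundaries` (last sample
#' index of each stitched trial except the final one) and `anchors`
#' (sample indices of the stride anchor events, left heel strikes).
#'
#' @param value Numeric signal.
#' @param rate Sampling rate in Hz.
#' @param time Optional time stamps; defaults to `(0:(n-1))/rate`.
#' @param stage Processing stage string.
#' @param boundaries Integer junction indices (see above).
#' @param anchors Integer stride-anchor sample indices.
#' @return A `scalar_traj` tibble.
#' @export
scalar_traj <- function(value, rate, time = NULL, stage = "raw",
                        boundaries = integer(), anchors = integer()) {
  if (!is_scalar_number(rate) || rate <= 0) {
    stop_validation("`rate` must be a single positive number (Hz).")
  }
  value <- as.numeric(value)
  time <- time %||% (seq_along(value) - 1) / rate
  structure(tibble(time = time, value = value),
            class = c("scalar_traj", class(tibble())),
            rate = rate, stage = stage,
            boundaries = as.integer(boundaries),
            anchors = as.integer(anchors))
}

#' @rdname scalar_traj
#' @param x A `scalar_traj`.
#' @export
signal_rate <- function(x) attr(x, "rate")

#' @rdname scalar_traj
#' @export
signal_stage <- function(x) attr(x, "stage")

#' @rdname scalar_traj
#' @export
trial_boundaries <- function(x) attr(x, "boundaries") %||% integer()

#' @rdname scalar_traj
#' @export
stride_anchors <- function(x) attr(x, "anchors") %||% integer()

#' @export
print.scalar_traj <- function(x, ...) {
  cat(sprintf("<scalar_traj> %d samples at %g Hz, stage `%s`\n",
              nrow(x), attr(x, "rate"), attr(x, "stage")))
  NextMethod()
}

restamp <- function(x, tpl, stage = attr(tpl, "stage"),
                    boundaries = attr(tpl, "boundaries"),
                    anchors = attr(tpl, "anchors")) {
  structure(x, class = c("scalar_traj", class(tibble())),
            rate = attr(tpl, "rate"), stage = stage,
            boundaries = as.integer(boundaries %||% integer()),
            anchors = as.integer(anchors %||% integer()))
}

#' Medio-lateral centre-of-mass and centre-of-pressure surrogates
#'
#' `com_surrogate()` is the per-frame mean of the four pelvis markers (RPSI,
#' LPSI, RASI, LASI) along the medio-lateral axis, a surrogate for the M/L
#' motion of the centre of mass. `cop_surrogate()` is the per-frame mean of
#' the two heel markers (RHEE, LHEE), a surrogate for the centre of pressure.
#' `relative_ml_signal()` forms y(t) = CoM_ML(t) - CoP_ML(t), the raw input
#' of the stability analysis.
#'
#' Both surrogates depend only on the medio-lateral coordinate, so they are
#' invariant to antero-posterior and vertical translations of the markers.
#'
#' @param mts A [marker_set()] with complete frames (see
#'   [drop_invalid_frames()]).
#' @return A [scalar_traj()] at stage `"raw"`.
#' @export
com_surrogate <- function(mts) {
  pelvis <- c("RPSI", "LPSI", "RASI", "LASI")
  check_markers_present(mts, pelvis, "com_surrogate")
  cols <- matrix(unlist(lapply(pelvis, function(l) marker_axis(mts, l, "ml"))),
                 nrow = nrow(mts))
  if (anyNA(cols)) {
    stop_validation(
      "pelvis markers contain missing frames; run drop_invalid_frames() first.")
  }
  scalar_traj(rowMeans(cols), rate = marker_rate(mts), time = mts$time)
}

#' @rdname com_surrogate
#' @export
cop_surrogate <- function(mts) {
  heels <- c("RHEE", "LHEE")
  check_markers_present(mts, heels, "cop_surrogate")
  cols <- matrix(unlist(lapply(heels, function(l) marker_axis(mts, l, "ml"))),
                 nrow = nrow(mts))
  if (anyNA(cols)) {
    stop_validation(
      "heel markers contain missing frames; run drop_invalid_frames() first.")
  }
  scalar_traj(rowMeans(cols), rate = marker_rate(mts), time = mts$time)
}

#' @rdname com_surrogate
#' @param com,cop Scalar trajectories of equal length and rate.
#' @export
relative_ml_signal <- function(com, cop) {
  if (nrow(com) != nrow(cop)) {
    stop_validation("CoM and CoP signals differ in length.")
  }
  if (!isTRUE(all.equal(signal_rate(com), signal_rate(cop)))) {
    stop_validation("CoM and CoP signals differ in sampling rate.")
  }
  restamp(tibble(time = com$time, value = com$value - cop$value), com,
          stage = "raw")
}

#' Mean-normalize a trajectory
#'
#' Subtracts the trial mean so the output averages to zero. Applied per trial
#' before stitching.
#'
#' @param y A [scalar_traj()].
#' @return The zero-mean trajectory at stage `"normalized"`.
#' @export
mean_normalize <- function(y) {
  if (nrow(y) == 0L) {
    stop_validation("cannot normalize an empty trajectory.")
  }
  out <- tibble(time = y$time, value = y$value - mean(y$value))
  restamp(out, y, stage = "normalized")
}

#' Stitch per-trial trajectories into one long record
#'
#' Concatenates mean-normalized trials in the given order. Junction indices
#' are recorded so downstream neighbour and regression computations can
#' exclude windows spanning the artificial joins; stride anchors are shifted
#' into the stitched coordinate system. Time is re-based to a continuous
#' axis at the common rate.
#'
#' @param trials List of [scalar_traj()] at stage `"normalized"`, same rate.
#' @return One `scalar_traj` at stage `"stitched"`.
#' @export
stitch_trials <- function(trials) {
  if (!is.list(trials) || length(trials) == 0L) {
    stop_validation("`trials` must be a non-empty list of scalar_traj.")
  }
  rates <- vapply(trials, signal_rate, numeric(1))
  if (max(rates) - min(rates) > 1e-9) {
    stop_validation("all trials must share the same sampling rate.")
  }
  stages <- vapply(trials, signal_stage, character(1))
  if (!all(stages == "normalized")) {
    stop_validation("all trials must be at stage `normalized` before stitching.")
  }
  lens <- vapply(trials, nrow, integer(1))
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  value <- unlist(lapply(trials, function(t) t$value), use.names = FALSE)
  anchors <- unlist(Map(function(t, off) stride_anchors(t) + off,
                        trials, offsets), use.names = FALSE)
  boundaries <- cumsum(lens)
  boundaries <- boundaries[-length(boundaries)]
  scalar_traj(value, rate = rates[1], stage = "stitched",
              boundaries = boundaries, anchors = anchors)
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies an order-`order` Butterworth low-pass filter forward and backward
#' (`signal::filtfilt`), the biomechanics convention: zero phase shift at the
#' cost of doubling the effective order.
#'
#' @param y A [scalar_traj()] at stage `"stitched"` (or `"normalized"` for
#'   single-trial use).
#' @param cutoff Cutoff frequency in Hz (default 10); must be below Nyquist.
#' @param order Filter order (default 4).
#' @return The filtered trajectory at stage `"filtered"`.
#' @export
lowpass_filter <- function(y, cutoff = 10, order = 4) {
  rate <- signal_rate(y)
  if (!is_scalar_number(cutoff) || cutoff <= 0 || cutoff >= rate / 2) {
    stop_validation(sprintf(
      "`cutoff` must lie in (0, Nyquist = %g Hz).", rate / 2))
  }
  if (!signal_stage(y) %in% c("stitched", "normalized")) {
    stop_validation("filter expects a `stitched` (or `normalized`) trajectory.")
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  filt <- signal::filtfilt(bf, y$value)
  out <- tibble(time = y$time, value = as.numeric(filt))
  restamp(out, y, stage = "filtered")
}

#' Phase-space trajectory of a scalar signal
#'
#' Differentiates Y(t) with central finite differences (one-sided at the
#' ends; exact for linear signals) to form the planar state
#' m(t) = \[Y(t), dY/dt(t)\].
#'
#' @param Y A [scalar_traj()] of length at least 3.
#' @return A `phase_traj` tibble with columns `time`, `y`, `ydot` and the
#'   same rate/boundary/anchor attributes.
#' @export
differentiate <- function(Y) {
  if (nrow(Y) < 3L) {
    stop_validation("need at least 3 samples to differentiate.")
  }
  rate <- signal_rate(Y)
  ydot <- pracma::gradient(Y$value, h1 = 1 / rate)
  structure(tibble(time = Y$time, y = Y$value, ydot = as.numeric(ydot)),
            class = c("phase_traj", class(tibble())),
            rate = rate, stage = signal_stage(Y),
            boundaries = trial_boundaries(Y), anchors = stride_anchors(Y))
}

#' @export
print.phase_traj <- function(x, ...) {
  cat(sprintf("<phase_traj> %d samples at %g Hz\n", nrow(x), attr(x, "rate")))
  NextMethod()
}
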