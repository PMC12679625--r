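#' Detect heel strikes, stride times and cadence
#'
#' Coordinate-based event detection: for each side, the heel marker's
#' antero-posterior position relative to the pelvis-centroid A/P position is
#' computed; its positive peaks mark heel strikes (the heel is maximally
#' ahead of the advancing pelvis at foot contact). Stride times come from
#' successive same-side strikes, cadence from the merged step count over
#' elapsed time.
#'
#' @param mts A [marker_set()] with heel and pelvis markers.
#' @param min_stride_s Minimum credible stride time in seconds; peaks closer
#'   than this are merged (default 1 s).
#' @param prominence_m Minimum height (m) of a relative-A/P peak above its
#'   mean to count as a strike (default 0.05 m).
#' @return A `gait_events` object: a list with `strikes` (tibble of side,
#'   sample index, time), `stride_times`, `stride_time` (median, the period
#'   T), `cadence` (steps/min), `n_strides`, and an `alternating` quality
#'   flag recording whether left and right strikes alternate.
#' @export
detect_gait_events <- function(mts, min_stride_s = 1, prominence_m = 0.05) {
  check_markers_present(mts, c("RHEE", "LHEE", "RPSI", "LPSI", "RASI", "LASI"),
                        "detect_gait_events")
  rate <- marker_rate(mts)
  pelvis_ap <- rowMeans(vapply(c("RPSI", "LPSI", "RASI", "LASI"),
                               function(l) marker_axis(mts, l, "ap"),
                               numeric(nrow(mts))))
  find_side <- function(label) {
    rel <- marker_axis(mts, label, "ap") - pelvis_ap
    rel <- rel - mean(rel)
    pk <- pracma::findpeaks(rel,
                            minpeakheight = prominence_m,
                            minpeakdistance = max(2L, round(min_stride_s * rate)))
    if (is.null(pk)) integer() else sort(pk[, 2])
  }
  left <- find_side("LHEE")
  right <- find_side("RHEE")
  if (length(left) < 4L || length(right) < 3L) {
    stop_insufficient(sprintf(
      "detected %d left / %d right heel strikes; need at least 3 strides.",
      length(left), length(right)))
  }
  stride_times <- c(diff(left), diff(right)) / rate
  merged <- rbind(tibble(side = "L", index = left),
                  tibble(side = "R", index = right))
  merged <- merged[order(merged$index), ]
  alternating <- all(merged$side[-1] != merged$side[-nrow(merged)])
  if (!alternating) {
    warn("left/right heel strikes do not strictly alternate; flagged in events.")
  }
  elapsed <- (merged$index[nrow(merged)] - merged$index[1]) / rate
  cadence <- 60 * (nrow(merged) - 1) / elapsed
  structure(list(
    strikes = tibble(side = merged$side, index = merged$index,
                     time = mts$time[merged$index]),
    left = left, right = right,
    stride_times = stride_times,
    stride_time = median(stride_times),
    cadence = cadence,
    n_strides = length(left) - 1L,
    alternating = alternating,
    rate = rate
  ), class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf(
    "<gait_events> %d strides, stride time %.3f s, cadence %.1f steps/min%s\n",
    x$n_strides, x$stride_time, x$cadence,
    if (x$alternating) "" else " [non-alternating]"))
  invisible(x)
}

#' Trim boundary strides from a trial
#'
#' Removes the samples before the (n_trim+1)-th and after the
#' (last - n_trim)-th anchor-side heel strike, discarding gait initiation and
#' termination. With `n_trim = 0` the trajectory is returned unchanged. The
#' retained anchor strikes are re-indexed into the trimmed signal and stored
#' as its stride anchors; the `time` column keeps original elapsed time.
#'
#' @param y A [scalar_traj()] for the same trial as `events`.
#' @param events A [detect_gait_events()] result.
#' @param n_trim Strides to discard at each end (default 2).
#' @param side Anchor side, `"left"` or `"right"`.
#' @return The trimmed trajectory with stride anchors attached.
#' @export
trim_boundary_strides <- function(y, events, n_trim = 2, side = c("left", "right")) {
  side <- match.arg(side)
  strikes <- if (side == "left") events$left else events$right
  n_strides <- length(strikes) - 1L
  if (n_trim == 0L) {
    return(restamp(y[, c("time", "value")], y, anchors = strikes))
  }
  if (n_strides < 2L * n_trim + 1L) {
    stop_insufficient(sprintf(
      "trial has %d strides; trimming %d from each end needs at least %d.",
      n_strides, n_trim, 2L * n_trim + 1L))
  }
  keep <- strikes[(n_trim + 1L):(length(strikes) - n_trim)]
  lo <- keep[1]
  hi <- keep[length(keep)]
  out <- y[lo:hi, c("time", "value")]
  restamp(out, y, anchors = keep - lo + 1L)
}
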