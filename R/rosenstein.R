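#' Short-term Lyapunov exponent by the Rosenstein algorithm
#'
#' For each reference state the nearest neighbour is located outside a
#' Theiler window (default one stride period) and, for stitched data, within
#' the same trial segment so the artificial junctions never enter the
#' statistic. The mean logarithmic divergence curve <ln d_j(i)> is tracked
#' over a horizon of one stride and the short-term exponent is the
#' least-squares slope of the curve over the window \[0, 0.5 T\] (half a gait
#' cycle), in 1/s; the stride-normalized slope (x T) is also reported. The
#' slope is invariant to uniform amplitude scaling of the signal.
#'
#' @param emb An [delay_embed()] result.
#' @param stride_time Stride period T in seconds (defaults to the value
#'   carried by the embedding).
#' @param fit_fraction Upper end of the fit window as a fraction of T
#'   (default 0.5).
#' @param theiler_strides Theiler exclusion in strides (default 1).
#' @param max_refs Cap on the number of reference points (default 1000,
#'   deterministic even subsample).
#' @param horizon_s Divergence-tracking horizon in seconds (default T, or
#'   the upper end of `fit_window` when that is longer).
#' @param fit_window Optional `c(lo, hi)` in seconds, overriding the
#'   `[0, fit_fraction * T]` default. Useful for continuous chaotic
#'   benchmarks, where the first pseudo-period of the divergence curve is an
#'   orientation transient and the slope is fitted on the linear region
#'   beyond it.
#' @return A `gait_rosenstein` object: `curve` (tibble `time`,
#'   `mean_log_divergence`), `max_le_s` (1/s), `le_s_per_stride`, `fit_r2`,
#'   `fit_window`, `n_refs`, `low_quality` flag.
#' @export
rosenstein_le <- function(emb, stride_time = emb$stride_time,
                          fit_fraction = 0.5, theiler_strides = 1,
                          max_refs = 1000, horizon_s = NULL,
                          fit_window = NULL) {
  if (is.null(stride_time) || !is_scalar_number(stride_time) ||
      stride_time <= 0) {
    stop_validation("`stride_time` (T, seconds) must be a positive number.")
  }
  S <- emb$states
  m <- ncol(S)
  rate <- emb$rate
  T_samp <- max(1L, round(stride_time * rate))
  theiler <- max(1L, round(theiler_strides * T_samp))
  fit_window <- fit_window %||% c(0, fit_fraction * stride_time)
  if (length(fit_window) != 2L || fit_window[2] <= fit_window[1]) {
    stop_validation("`fit_window` must be c(lo, hi) seconds with hi > lo.")
  }
  horizon <- max(2L, round(max(horizon_s %||% stride_time,
                               fit_window[2]) * rate))
  # states usable as reference/neighbour: unmasked with a full horizon that
  # stays inside one trial segment
  valid <- which(!emb$mask &
                   seq_len(m) + horizon <= m &
                   emb$segment == segment_of(seq_len(m) + horizon,
                                             emb$boundaries))
  if (length(valid) < 2L) {
    stop_insufficient("no usable reference states for the divergence curve.")
  }
  n_strides_avail <- floor(m / T_samp)
  if (n_strides_avail < 10L) {
    warn(sprintf(
      "only about %d strides of embedded data; the Rosenstein estimate may be unreliable below 10.",
      n_strides_avail))
  }
  refs <- subsample_idx(valid, max_refs)
  sq <- colSums(S[, valid, drop = FALSE]^2)
  nb_of <- integer(length(refs))
  keep <- logical(length(refs))
  for (start in seq(1L, length(refs), by = 128L)) {
    block <- refs[start:min(start + 127L, length(refs))]
    Sb <- S[, block, drop = FALSE]
    D2 <- outer(rep(1, length(valid)), colSums(Sb^2)) + sq -
      2 * crossprod(S[, valid, drop = FALSE], Sb)
    for (bi in seq_along(block)) {
      j <- block[bi]
      d2 <- D2[, bi]
      d2[abs(valid - j) <= theiler] <- Inf
      d2[d2 <= 0] <- Inf          # exclude exact duplicates
      nb <- which.min(d2)
      i <- start + bi - 1L
      if (is.finite(d2[nb])) {
        nb_of[i] <- valid[nb]
        keep[i] <- TRUE
      }
    }
  }
  refs <- refs[keep]
  nbs <- nb_of[keep]
  if (length(refs) == 0L) {
    stop_insufficient("no valid neighbours found outside the Theiler window.")
  }
  steps <- 0:horizon
  mean_log_div <- vapply(steps, function(i) {
    diff <- S[, refs + i, drop = FALSE] - S[, nbs + i, drop = FALSE]
    dj <- sqrt(colSums(diff^2))
    dj <- dj[dj > 0]
    if (length(dj) == 0L) NA_real_ else mean(log(dj))
  }, numeric(1))
  curve <- tibble(time = steps / rate, mean_log_divergence = mean_log_div)
  fit_pts <- curve[curve$time >= fit_window[1] - 1e-12 &
                     curve$time <= fit_window[2] + 1e-12 &
                     is.finite(curve$mean_log_divergence), ]
  if (nrow(fit_pts) < 3L) {
    stop_insufficient("divergence curve too short for the slope fit.")
  }
  fit <- lm(mean_log_divergence ~ time, data = fit_pts)
  slope <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  low_quality <- is.finite(r2) && r2 < 0.5
  if (low_quality) {
    warn(sprintf("divergence-curve fit is poor (R^2 = %.2f); slope flagged.",
                 r2))
  }
  structure(list(
    curve = curve,
    max_le_s = slope,
    le_s_per_stride = slope * stride_time,
    fit_r2 = r2,
    fit_window = fit_window,
    n_refs = length(refs),
    stride_time = stride_time,
    low_quality = low_quality
  ), class = "gait_rosenstein")
}

#' @export
print.gait_rosenstein <- function(x, ...) {
  cat(sprintf(
    "<gait_rosenstein> max LE_S = %.4f 1/s (%.4f per stride), fit R^2 = %.3f over [%.3g, %.3g] s, %d references%s\n",
    x$max_le_s, x$le_s_per_stride, x$fit_r2, x$fit_window[1],
    x$fit_window[2], x$n_refs,
    if (x$low_quality) " [low-quality fit]" else ""))
  invisible(x)
}

#' @export
tidy.gait_rosenstein <- function(x, ...) {
  x$curve
}

#' @export
glance.gait_rosenstein <- function(x, ...) {
  tibble(
    max_le_s = x$max_le_s,
    le_s_per_stride = x$le_s_per_stride,
    fit_r2 = x$fit_r2,
    fit_window_s = x$fit_window[2],
    n_refs = x$n_refs,
    low_quality = x$low_quality
  )
}
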