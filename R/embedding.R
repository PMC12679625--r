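#' Average mutual information of a signal with its lagged copy
#'
#' Equiprobable (rank-based) binning with `bins` bins per margin, the
#' density-estimation-free default. Used to select the embedding delay.
#'
#' @param x Numeric signal or [scalar_traj()].
#' @param max_lag Largest lag (samples) to evaluate.
#' @param bins Bins per margin; default `ceiling(sqrt(length(x)))`.
#' @return Tibble with columns `lag` and `ami` (nats).
#' @export
average_mutual_information <- function(x, max_lag, bins = NULL) {
  if (inherits(x, "scalar_traj")) x <- x$value
  L <- length(x)
  if (max_lag >= L - 1L) {
    stop_validation("`max_lag` must be smaller than the signal length.")
  }
  bins <- bins %||% ceiling(sqrt(L))
  b <- ceiling(rank(x, ties.method = "first") * bins / L)
  ami <- vapply(seq_len(max_lag), function(k) {
    n <- L - k
    joint <- tabulate((b[1:n] - 1L) * bins + b[(k + 1L):L], nbins = bins * bins)
    p <- joint / n
    pi_ <- tabulate(b[1:n], nbins = bins) / n
    pj_ <- tabulate(b[(k + 1L):L], nbins = bins) / n
    nz <- p > 0
    ij <- which(nz)
    i <- ((ij - 1L) %/% bins) + 1L
    j <- ((ij - 1L) %% bins) + 1L
    sum(p[nz] * log(p[nz] / (pi_[i] * pj_[j])))
  }, numeric(1))
  tibble(lag = seq_len(max_lag), ami = ami)
}

#' Optimal embedding delay
#'
#' The delay is the first local minimum of the average mutual information
#' over lags `1..max_lag` (the standard prescription). Binned AMI estimates
#' jitter from lag to lag, so the curve is smoothed with a five-point moving
#' average before the minimum search and lags below 3 samples are not
#' selectable (at gait sampling rates they carry no phase-space
#' information). If the smoothed curve has no minimum in range, the
#' fallback is the first lag at which the autocorrelation drops below
#' 1 - 1/e.
#'
#' @param Y A [scalar_traj()] or numeric signal.
#' @param max_lag Largest lag to scan; defaults to two seconds of samples
#'   (capped at a third of the signal).
#' @param bins Passed to [average_mutual_information()].
#' @param rate Sampling rate, required when `Y` is a bare numeric vector.
#' @return Delay in samples (integer >= 1).
#' @export
optimal_delay <- function(Y, max_lag = NULL, bins = NULL, rate = NULL) {
  if (inherits(Y, "scalar_traj")) {
    rate <- signal_rate(Y)
    x <- Y$value
  } else {
    x <- as.numeric(Y)
  }
  if (sd(x) == 0) {
    stop_validation("signal is constant; no meaningful embedding delay.")
  }
  max_lag <- max_lag %||% min(round(2 * (rate %||% 100)),
                              floor(length(x) / 3))
  ami <- average_mutual_information(x, max_lag = max_lag, bins = bins)$ami
  sm <- as.numeric(stats::filter(ami, rep(1 / 5, 5), sides = 2))
  # first k (>= 3) where the smoothed curve stops decreasing
  rising <- which(sm[-length(sm)] <= sm[-1])
  rising <- rising[rising >= 3L]
  if (length(rising) > 0L) {
    return(as.integer(rising[1]))
  }
  r <- acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  below <- which(r < 1 - exp(-1))
  if (length(below) > 0L) {
    return(as.integer(below[1]))
  }
  as.integer(max_lag)
}

# Fraction of false nearest neighbours when growing the planar-block
# embedding from n to n+1 delayed copies of m(t) = [Y, Ydot].
false_nearest_fraction <- function(phase, tau, n, theiler,
                                   rtol = 15, atol = 2, max_refs = 1500) {
  L <- nrow(phase)
  span_next <- (n + 1L) * tau
  if (L <= span_next + 1L) {
    stop_validation("signal too short for the requested embedding dimension.")
  }
  m_cols <- L - span_next            # columns with room for the n+1 block
  Y <- phase$y
  Yd <- phase$ydot
  # states for dimension n, restricted to columns that also exist at n+1
  d <- 2L * (n + 1L)
  S <- matrix(0, nrow = d, ncol = m_cols)
  for (k in 0:n) {
    idx <- seq_len(m_cols) + k * tau
    S[2L * k + 1L, ] <- Y[idx]
    S[2L * k + 2L, ] <- Yd[idx]
  }
  extra_idx <- seq_len(m_cols) + span_next
  E <- rbind(Y[extra_idx], Yd[extra_idx])
  size <- sqrt(mean(S^2))
  refs <- subsample_idx(seq_len(m_cols), max_refs)
  sq <- colSums(S^2)
  n_false <- 0L
  n_tot <- 0L
  for (start in seq(1L, length(refs), by = 256L)) {
    block <- refs[start:min(start + 255L, length(refs))]
    D2 <- outer(rep(1, m_cols), sq[block]) + sq - 2 * crossprod(S, S[, block, drop = FALSE])
    for (bi in seq_along(block)) {
      j <- block[bi]
      d2 <- D2[, bi]
      d2[abs(seq_len(m_cols) - j) <= theiler] <- Inf
      nb <- which.min(d2)
      dist_d <- sqrt(max(d2[nb], 0))
      if (!is.finite(dist_d)) next
      extra <- sqrt((E[1, j] - E[1, nb])^2 + (E[2, j] - E[2, nb])^2)
      n_tot <- n_tot + 1L
      if (dist_d == 0) {
        # exact recurrence (strictly periodic signal): false only if the
        # added coordinates separate it
        if (extra / size > atol) n_false <- n_false + 1L
      } else {
        dist_d1 <- sqrt(dist_d^2 + extra^2)
        if (extra / dist_d > rtol || dist_d1 / size > atol) {
          n_false <- n_false + 1L
        }
      }
    }
  }
  if (n_tot == 0L) {
    stop_insufficient("no valid neighbours found for the FNN statistic.")
  }
  n_false / n_tot
}

#' Optimal embedding dimension by false nearest neighbours
#'
#' Tests n = 0, 1, 2, ... delayed copies of the planar state
#' m(t) = \[Y, dY/dt\] (total dimension 2(n+1)) and returns the smallest n
#' whose false-nearest-neighbour fraction falls below `threshold`
#' (distance-ratio test, ratio threshold 15, plus an attractor-size check).
#' Temporally correlated neighbours are excluded with a Theiler window of
#' one stride period.
#'
#' @param phase A `phase_traj` from [differentiate()].
#' @param tau Embedding delay in samples (see [optimal_delay()]).
#' @param max_n Largest n to test; reached with a warning if no n passes.
#' @param threshold FNN fraction below which n is accepted (default 0.05).
#' @param theiler Theiler exclusion in samples; default one stride period
#'   when `stride_time` is given, else `tau`.
#' @param stride_time Stride period in seconds (sets the Theiler window).
#' @param rtol Distance-ratio threshold for a false neighbour (default 15).
#' @return The embedding index n (integer >= 0).
#' @export
optimal_dimension <- function(phase, tau, max_n = 8, threshold = 0.05,
                              theiler = NULL, stride_time = NULL, rtol = 15) {
  rate <- attr(phase, "rate")
  theiler <- theiler %||%
    if (!is.null(stride_time)) round(stride_time * rate) else tau
  if (nrow(phase) <= max_n * tau + 10L) {
    stop_validation("signal too short for the requested `max_n` and `tau`.")
  }
  for (n in 0:max_n) {
    f <- false_nearest_fraction(phase, tau = tau, n = n, theiler = theiler,
                                rtol = rtol)
    if (f < threshold) {
      return(as.integer(n))
    }
  }
  warn(sprintf("FNN fraction never fell below %.0f%%; using max_n = %d.",
               100 * threshold, max_n))
  as.integer(max_n)
}

#' Time-delay embedding of the phase trajectory
#'
#' Builds M(t) = \[m(t), m(t+tau), ..., m(t+n tau)\] with
#' m(t) = \[Y(t), dY/dt(t)\], one column per time sample, total dimension
#' d = 2(n+1). Columns whose delayed window spans a stitched-trial junction
#' are masked out of all downstream neighbour and regression computations.
#'
#' @param phase A `phase_traj` from [differentiate()].
#' @param tau Delay in samples (>= 1).
#' @param n Embedding index (>= 0); `n = 0` is the identity embedding.
#' @param stride_time Optional stride period T in seconds, carried along for
#'   the monodromy and Rosenstein estimators.
#' @return An `embedded_system`: list with the `states` matrix (d x m),
#'   `tau`, `n`, `d`, `rate`, `boundaries`, logical junction `mask`,
#'   `anchors` and `stride_time`.
#' @export
delay_embed <- function(phase, tau, n, stride_time = NULL) {
  tau <- as.integer(tau)
  n <- as.integer(n)
  if (tau < 1L || n < 0L) {
    stop_validation("`tau` must be >= 1 sample and `n` >= 0.")
  }
  L <- nrow(phase)
  if (n * tau >= L) {
    stop_validation("n * tau must be smaller than the signal length.")
  }
  m <- L - n * tau
  d <- 2L * (n + 1L)
  S <- matrix(0, nrow = d, ncol = m)
  for (k in 0:n) {
    idx <- seq_len(m) + k * tau
    S[2L * k + 1L, ] <- phase$y[idx]
    S[2L * k + 2L, ] <- phase$ydot[idx]
  }
  boundaries <- attr(phase, "boundaries") %||% integer()
  seg_start <- segment_of(seq_len(m), boundaries)
  seg_end <- segment_of(seq_len(m) + n * tau, boundaries)
  mask <- seg_start != seg_end
  structure(list(states = S, tau = tau, n = n, d = d,
                 rate = attr(phase, "rate"),
                 boundaries = boundaries,
                 segment = seg_start,
                 mask = mask,
                 anchors = attr(phase, "anchors") %||% integer(),
                 stride_time = stride_time),
            class = "embedded_system")
}

#' @export
print.embedded_system <- function(x, ...) {
  cat(sprintf(
    "<embedded_system> d = %d (n = %d, tau = %d samples), %d columns (%d masked)\n",
    x$d, x$n, x$tau, ncol(x$states), sum(x$mask)))
  invisible(x)
}
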