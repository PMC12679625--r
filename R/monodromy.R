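#' Estimate the one-stride monodromy matrix and Floquet spectrum
#'
#' The monodromy matrix maps the embedded state across one stride period T:
#' Phi = M(t+T) M(t)^-1 on a Poincare section anchored at a consistent gait
#' phase (each left heel strike by default). The estimator is a least-squares
#' one-period state-transition fit over stride-separated state pairs:
#' deviations of the section states from their section mean are collected
#' into matrices D0 and DT and Phi minimizes ||DT - Phi D0||_F, solved
#' through the SVD pseudo-inverse. This reduces to M(T) M(0)^-1 when exactly
#' d independent anchors are used, and centring makes the fit exact for any
#' affine stride-to-stride map (the state recursion of a kicked linear
#' oscillator).
#'
#' Because one stride contributes only one pair per section, the fit pools
#' sections at `n_phases` evenly spaced phase offsets from the anchors, each
#' centred on its own section mean. For deviation dynamics that do not
#' change across the cycle (exactly true for linearized time-invariant sway
#' dynamics, and the working approximation for gait) every section shares
#' the same one-period propagator, so pooling multiplies the usable pairs by
#' `n_phases` without biasing the spectrum; estimating multipliers at
#' several section phases is likewise established practice for orbital
#' stability of gait.
#'
#' The eigenvalues of Phi are the Floquet multipliers (FM); the Floquet
#' exponents are their principal logarithms divided by T (identical to the
#' eigenvalues of the principal matrix logarithm of Phi over T whenever Phi
#' is diagonalizable), and their real parts are the long-term Lyapunov
#' exponents (1/s). A multiplier on the negative real axis has no real
#' logarithm on the principal branch; such spectra are flagged with a
#' branch-cut warning rather than silently resolved.
#'
#' @param emb An [delay_embed()] result. Anchor columns and the stride
#'   period default to the ones carried by the embedding.
#' @param stride_time Stride period T in seconds.
#' @param anchors Anchor sample indices (columns of the embedding).
#' @param min_pairs Minimum usable pooled pairs; default d + 1.
#' @param n_phases Number of evenly spaced section phases per stride
#'   (default 24, capped at the stride length in samples). `1` uses only
#'   the anchor-phase section.
#' @param cond_max Condition-number cap for the pooled centred deviation
#'   matrix (default 1e8); beyond it an ill-conditioning error is raised.
#' @param energy SVD energy threshold in (0, 1\]: the fit is restricted to
#'   the leading principal directions of the deviation data explaining this
#'   fraction of variance (at least two), the rank-truncation used in
#'   subspace/dynamic-mode identification. Delayed copies of a smooth
#'   planar signal are strongly collinear, so directions beyond the
#'   dynamically occupied subspace carry mostly observation noise and would
#'   contribute spurious multipliers. `1` disables truncation.
#' @return A `gait_monodromy` object: `phi`, complex `fm` spectrum,
#'   `exponents` (1/s), `mean_abs_fm`, `max_abs_fm`, `max_le_l`,
#'   `condition_number`, `n_pairs`, `n_sections`, `stride_time`,
#'   `branch_warning`.
#' @examples
#' sim <- simulate_linear_oscillator(zeta = 0.1, omega = 2 * pi, T = 1,
#'                                   n_strides = 60, rate = 120, seed = 1)
#' emb <- delay_embed(differentiate(sim), tau = 1, n = 0, stride_time = 1)
#' glance(estimate_monodromy(emb))
#' @export
estimate_monodromy <- function(emb, stride_time = emb$stride_time,
                               anchors = emb$anchors,
                               min_pairs = NULL, n_phases = 24,
                               cond_max = 1e8, energy = 0.99) {
  if (is.null(stride_time) || !is_scalar_number(stride_time) ||
      stride_time <= 0) {
    stop_validation("`stride_time` (T, seconds) must be a positive number.")
  }
  S <- emb$states
  m <- ncol(S)
  d <- emb$d
  T_samp <- round(stride_time * emb$rate)
  base <- as.integer(anchors)
  n_phases <- max(1L, min(as.integer(n_phases), T_samp))
  phases <- unique(round(seq(0, T_samp - 1,
                             length.out = n_phases + 1))[seq_len(n_phases)])
  usable_section <- function(a) {
    # the first and last record samples carry one-sided derivative estimates
    a <- a[a >= 2L & a + T_samp <= m - 1L]
    a[!emb$mask[a] & !emb$mask[a + T_samp] &
        emb$segment[a] == emb$segment[a + T_samp]]
  }
  D0 <- NULL
  DT <- NULL
  n_sections <- 0L
  for (ph in phases) {
    a <- usable_section(base + ph)
    if (length(a) < 3L) next
    S0 <- S[, a, drop = FALSE]
    ST <- S[, a + T_samp, drop = FALSE]
    D0 <- cbind(D0, S0 - rowMeans(S0))
    DT <- cbind(DT, ST - rowMeans(ST))
    n_sections <- n_sections + 1L
  }
  K <- if (is.null(D0)) 0L else ncol(D0)
  K_base <- length(usable_section(base))
  min_pairs <- min_pairs %||% (d + 1L)
  if (K < max(min_pairs, d + 1L) || K_base < 3L) {
    stop_insufficient(sprintf(
      "only %d usable stride-separated state pairs (%d at the anchor phase); need at least %d for a %dx%d monodromy fit.",
      K, K_base, max(min_pairs, d + 1L), d, d))
  }
  sv <- svd(D0)
  r <- max(2L, which(cumsum(sv$d^2) / sum(sv$d^2) >= energy)[1])
  r <- min(r, d)
  cond <- sv$d[1] / sv$d[r]
  if (!is.finite(cond) || cond > cond_max) {
    stop_conditioning(sprintf(
      "centred anchor-state matrix is ill-conditioned (condition number %.3g > %.3g); the stride-to-stride deviations do not span the embedding space.",
      cond, cond_max))
  }
  Ur <- sv$u[, seq_len(r), drop = FALSE]
  Vr <- sv$v[, seq_len(r), drop = FALSE]
  # reduced-rank one-period propagator on the dominant deviation subspace
  phi_r <- crossprod(Ur, DT %*% Vr) / rep(sv$d[seq_len(r)],
                                          each = r)
  phi <- Ur %*% phi_r %*% t(Ur)
  fm <- eigen(phi_r, only.values = TRUE)$values
  branch <- any(abs(Im(fm)) < 1e-10 & Re(fm) < 0)
  if (branch) {
    warn("Floquet multiplier on the negative real axis: principal-branch logarithm is discontinuous here; exponents flagged.")
  }
  exponents <- log(as.complex(fm)) / stride_time
  structure(list(
    phi = phi,
    fm = fm,
    exponents = exponents,
    mean_abs_fm = mean(Mod(fm)),
    max_abs_fm = max(Mod(fm)),
    max_le_l = max(Re(exponents)),
    condition_number = cond,
    n_pairs = K,
    n_sections = n_sections,
    rank = r,
    stride_time = stride_time,
    branch_warning = branch
  ), class = "gait_monodromy")
}

#' Floquet spectrum of a given monodromy matrix
#'
#' Convenience constructor when Phi is known directly (e.g. analytic test
#' matrices) rather than estimated from data.
#'
#' @param phi A square numeric matrix.
#' @param stride_time Period T in seconds.
#' @return A `gait_monodromy` object (with `n_pairs = NA`).
#' @export
floquet_from_phi <- function(phi, stride_time) {
  if (!is.matrix(phi) || nrow(phi) != ncol(phi)) {
    stop_validation("`phi` must be a square matrix.")
  }
  fm <- eigen(phi, only.values = TRUE)$values
  exponents <- log(as.complex(fm)) / stride_time
  structure(list(
    phi = phi, fm = fm, exponents = exponents,
    mean_abs_fm = mean(Mod(fm)),
    max_abs_fm = max(Mod(fm)),
    max_le_l = max(Re(exponents)),
    condition_number = NA_real_,
    n_pairs = NA_integer_,
    n_sections = NA_integer_,
    stride_time = stride_time,
    branch_warning = any(abs(Im(fm)) < 1e-10 & Re(fm) < 0)
  ), class = "gait_monodromy")
}

#' @export
print.gait_monodromy <- function(x, ...) {
  cat(sprintf(
    "<gait_monodromy> d = %d, T = %.3f s, %s pairs\n  mean |FM| = %.4f, max |FM| = %.4f, max LE_L = %.4f 1/s\n",
    nrow(x$phi), x$stride_time,
    ifelse(is.na(x$n_pairs), "?", as.character(x$n_pairs)),
    x$mean_abs_fm, x$max_abs_fm, x$max_le_l))
  invisible(x)
}

#' Mean Floquet-multiplier magnitude
#'
#' @param res A `gait_monodromy`.
#' @return Mean of the eigenvalue magnitudes of the monodromy matrix.
#' @export
summarize_fm <- function(res) {
  if (length(res$fm) == 0L) {
    stop_validation("empty Floquet spectrum.")
  }
  mean(Mod(res$fm))
}

#' @export
tidy.gait_monodromy <- function(x, ...) {
  tibble(
    multiplier_re = Re(x$fm),
    multiplier_im = Im(x$fm),
    modulus = Mod(x$fm),
    exponent_re = Re(x$exponents),
    exponent_im = Im(x$exponents),
    exponent_re_per_stride = Re(x$exponents) * x$stride_time
  )
}

#' @export
glance.gait_monodromy <- function(x, ...) {
  tibble(
    mean_abs_fm = x$mean_abs_fm,
    max_abs_fm = x$max_abs_fm,
    max_le_l = x$max_le_l,
    max_le_l_per_stride = x$max_le_l * x$stride_time,
    stride_time = x$stride_time,
    n_pairs = x$n_pairs,
    condition_number = x$condition_number,
    branch_warning = x$branch_warning
  )
}

#' Stability assessment against the Floquet and Lyapunov criteria
#'
#' A periodic system is orbitally stable when every Floquet multiplier
#' satisfies |FM| <= 1, and Lyapunov-stable when its largest long-term
#' Lyapunov exponent satisfies LE <= 0 (both thresholds inclusive).
#'
#' @param monodromy A `gait_monodromy`.
#' @param rosenstein Optional `gait_rosenstein` result, echoed into the
#'   output for reporting.
#' @return One-row tibble with `stable_fm`, `stable_le`, the supporting
#'   values and a text `label`.
#' @export
assess_stability <- function(monodromy, rosenstein = NULL) {
  stable_fm <- monodromy$max_abs_fm <= 1
  stable_le <- monodromy$max_le_l <= 0
  label <- if (stable_fm && stable_le) {
    "stable"
  } else if (!stable_fm && !stable_le) {
    "unstable (FM and LE)"
  } else if (!stable_fm) {
    "unstable by FM criterion"
  } else {
    "unstable by LE criterion"
  }
  tibble(
    stable_fm = stable_fm,
    stable_le = stable_le,
    max_abs_fm = monodromy$max_abs_fm,
    max_le_l = monodromy$max_le_l,
    max_le_s = if (is.null(rosenstein)) NA_real_ else rosenstein$max_le_s,
    label = label
  )
}
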