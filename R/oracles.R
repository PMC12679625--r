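#' Analytic Floquet/Lyapunov ground truth for a linear system
#'
#' For the linear system xdot = A x sampled over a period T, the Floquet
#' multipliers are the eigenvalues of the matrix exponential exp(A T)
#' (computed by scaling-and-squaring, independent of the estimation path)
#' and the Lyapunov exponents are the real parts of the eigenvalues of A.
#'
#' @param A Square system matrix.
#' @param T Period in seconds.
#' @return List with complex `fm` and numeric `le` spectra, plus `phi`.
#' @export
analytic_floquet_oracle <- function(A, T) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop_validation("`A` must be a square matrix.")
  }
  phi <- pracma::expm(A * T)
  ev_phi <- eigen(phi, only.values = TRUE)$values
  ev_a <- eigen(A, only.values = TRUE)$values
  list(fm = ev_phi, le = Re(ev_a), phi = phi)
}

# System matrix of the damped linear oscillator xddot = -omega^2 x - 2 zeta
# omega xdot.
oscillator_matrix <- function(zeta, omega) {
  matrix(c(0, -omega^2, 1, -2 * zeta * omega), nrow = 2)
}

lorenz_field <- function(state, sigma, rho, beta) {
  c(sigma * (state[2] - state[1]),
    state[1] * (rho - state[3]) - state[2],
    state[1] * state[2] - beta * state[3])
}

lorenz_jacobian <- function(state, sigma, rho, beta) {
  matrix(c(-sigma, rho - state[3], state[2],
           sigma, -1, state[1],
           0, -state[1], -beta), nrow = 3)
}

# One fixed-step RK4 step for an autonomous field.
rk4_step <- function(x, h, f) {
  k1 <- f(x)
  k2 <- f(x + h / 2 * k1)
  k3 <- f(x + h / 2 * k2)
  k4 <- f(x + h * k3)
  x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Lyapunov spectrum of the Lorenz system by the Benettin QR method
#'
#' Integrates the Lorenz equations together with a full tangent basis
#' (fixed-step RK4) and re-orthonormalizes the basis by QR decomposition at
#' regular intervals, accumulating the logarithms of the diagonal of R. This
#' is the standard independent oracle for divergence-curve estimators of the
#' largest Lyapunov exponent (about 0.906 1/s at the canonical parameters).
#'
#' @param sigma,rho,beta Lorenz parameters.
#' @param duration Averaging time in seconds (after the transient).
#' @param transient Discarded settle-in time in seconds (default 10).
#' @param dt Integration step (default 0.005 s).
#' @param renorm_every QR renormalizations every this many steps.
#' @param x0 Initial state.
#' @return Numeric vector of the three Lyapunov exponents, sorted
#'   decreasing (1/s).
#' @export
benettin_lyapunov_lorenz <- function(sigma = 10, rho = 28, beta = 8 / 3,
                                     duration = 200, transient = 10,
                                     dt = 0.005, renorm_every = 10,
                                     x0 = c(1, 1, 20)) {
  f <- function(x) lorenz_field(x, sigma, rho, beta)
  x <- x0
  for (i in seq_len(round(transient / dt))) {
    x <- rk4_step(x, dt, f)
  }
  Q <- diag(3)
  sums <- numeric(3)
  n_steps <- round(duration / dt)
  step <- 0L
  while (step < n_steps) {
    for (k in seq_len(renorm_every)) {
      # propagate state and tangent basis together (RK4 on the extended
      # system, with the Jacobian evaluated along the internal stages)
      k1x <- f(x);                         k1q <- lorenz_jacobian(x, sigma, rho, beta) %*% Q
      x2 <- x + dt / 2 * k1x;              q2 <- Q + dt / 2 * k1q
      k2x <- f(x2);                        k2q <- lorenz_jacobian(x2, sigma, rho, beta) %*% q2
      x3 <- x + dt / 2 * k2x;              q3 <- Q + dt / 2 * k2q
      k3x <- f(x3);                        k3q <- lorenz_jacobian(x3, sigma, rho, beta) %*% q3
      x4 <- x + dt * k3x;                  q4 <- Q + dt * k3q
      k4x <- f(x4);                        k4q <- lorenz_jacobian(x4, sigma, rho, beta) %*% q4
      x <- x + dt / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
      Q <- Q + dt / 6 * (k1q + 2 * k2q + 2 * k3q + k4q)
      step <- step + 1L
      if (step >= n_steps) break
    }
    qr_ <- qr(Q)
    Q <- qr.Q(qr_)
    Rd <- diag(qr.R(qr_))
    sgn <- sign(Rd)
    Q <- Q %*% diag(sgn)
    sums <- sums + log(abs(Rd))
  }
  sort(sums / (n_steps * dt), decreasing = TRUE)
}
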