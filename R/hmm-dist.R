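#' Gamma step-length density with optional zero mass
#'
#' Density of the state-dependent step-length distribution: a gamma
#' distribution parameterized by mean and standard deviation (shape =
#' mean^2/sd^2, scale = sd^2/mean), optionally inflated with a point mass at
#' exactly zero. For `l > 0` the density is `(1 - zero_mass)` times the gamma
#' density; at `l = 0` it is the point mass itself.
#'
#' @param l step lengths in meters (>= 0, NA allowed).
#' @param mean,sd gamma mean and standard deviation, both > 0 (meters).
#' @param zero_mass probability mass at `l = 0`, in `[0, 1)`.
#' @return numeric vector of densities.
#' @examples
#' gamma_step_density(2, mean = 2, sd = sqrt(2))  # shape 2, scale 1
#' @export
gamma_step_density <- function(l, mean, sd, zero_mass = 0) {
  if (mean <= 0 || sd <= 0) stopf("mean and sd must be > 0")
  if (zero_mass < 0 || zero_mass >= 1) stopf("zero_mass must be in [0, 1)")
  if (any(l < 0, na.rm = TRUE)) stopf("step lengths must be >= 0")
  shape <- mean^2 / sd^2
  scale <- sd^2 / mean
  out <- (1 - zero_mass) * dgamma(l, shape = shape, scale = scale)
  out[!is.na(l) & l == 0] <- zero_mass
  out
}

#' von Mises turning-angle density
#'
#' Density of the circular von Mises distribution on `(-pi, pi]`:
#' `exp(kappa * cos(phi - mu)) / (2 * pi * I0(kappa))`, with `I0` the
#' modified Bessel function of order 0. `kappa = 0` gives the circular
#' uniform density `1 / (2 * pi)`.
#'
#' @param phi angles in radians (NA allowed).
#' @param mu mean direction in `(-pi, pi]`.
#' @param kappa concentration, >= 0.
#' @return numeric vector of densities.
#' @export
vonmises_density <- function(phi, mu = 0, kappa = 1) {
  if (kappa < 0) stopf("kappa must be >= 0")
  # exponentially scaled Bessel keeps this stable for large kappa
  exp(kappa * (cos(phi - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' von Mises cumulative distribution on (-pi, pi]
#'
#' CDF measured from the cut point at `-pi`, computed from the Fourier
#' series of the density (truncated when terms fall below 1e-14).
#'
#' @inheritParams vonmises_density
#' @param q quantiles in radians, in `(-pi, pi]`.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
pvonmises <- function(q, mu = 0, kappa = 1) {
  if (kappa < 0) stopf("kappa must be >= 0")
  out <- (q + pi) / (2 * pi)
  if (kappa > 0) {
    i0 <- besselI(kappa, 0, expon.scaled = TRUE)
    jmax <- ceiling(kappa + 10 * sqrt(kappa + 1) + 30)
    corr <- 0
    for (j in seq_len(jmax)) {
      r <- besselI(kappa, j, expon.scaled = TRUE) / i0
      if (r < 1e-14) break
      corr <- corr + (r / j) * (sin(j * (q - mu)) + (-1)^j * sin(j * mu))
    }
    out <- out + corr / pi
  }
  pmin(pmax(out, 0), 1)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) wrapped-Cauchy envelope rejection sampler; `kappa`
#' below 1e-8 falls back to the circular uniform.
#'
#' @param n number of draws.
#' @inheritParams vonmises_density
#' @return numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stopf("kappa must be >= 0")
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(wrap_angle(runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    m <- length(todo)
    u1 <- runif(m); u2 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(acc)) {
      u3 <- runif(sum(acc))
      out[todo[acc]] <- sign(u3 - 0.5) * acos(f[acc])
    }
    todo <- todo[!acc]
  }
  wrap_angle(out + mu)
}

#' Covariate-dependent transition probability matrix
#'
#' Builds the N x N row-stochastic transition matrix from the multinomial
#' logit link: for `i != j`, `eta_ij = beta[, (i,j)] . x` and
#' `gamma_ij = exp(eta_ij) / sum_k exp(eta_ik)` with `eta_ii = 0`. Columns of
#' `beta` are ordered row-major over off-diagonal pairs:
#' (1->2), (1->3), ..., (2->1), (2->3), ...
#'
#' @param beta coefficient matrix of shape `(1 + p) x N(N-1)`; the first row
#'   holds intercepts.
#' @param x covariate vector, either of length `p` (the leading 1 for the
#'   intercept is prepended) or of length `1 + p` (used as-is).
#' @return the N x N transition matrix; rows sum to 1.
#' @examples
#' beta <- matrix(0, 1, 6)          # 3 states, no covariates
#' transition_matrix(beta, numeric(0))  # all rows 1/3
#' @export
transition_matrix <- function(beta, x = numeric(0)) {
  beta <- as.matrix(beta)
  m <- ncol(beta)
  N <- (1 + sqrt(1 + 4 * m)) / 2
  if (N != round(N)) stopf("ncol(beta) must equal N*(N-1) for some integer N")
  N <- as.integer(N)
  if (length(x) == nrow(beta) - 1) x <- c(1, x)
  if (length(x) != nrow(beta))
    stopf("covariate vector length %d does not match nrow(beta) = %d",
          length(x), nrow(beta))
  eta <- crossprod(beta, x)
  if (any(!is.finite(eta))) stopf("non-finite linear predictor eta")
  C_transition_matrix(beta, as.numeric(x), N)
}

#' Stationary distribution of a transition matrix
#'
#' The unique probability vector `delta` with `delta %*% Gamma = delta`,
#' obtained from the linear system `delta (I - Gamma + U) = 1` with `U` the
#' all-ones matrix.
#'
#' @param Gamma a row-stochastic N x N matrix with positive entries.
#' @return numeric vector of length N summing to 1.
#' @export
stationary <- function(Gamma) {
  Gamma <- as.matrix(Gamma)
  N <- nrow(Gamma)
  if (ncol(Gamma) != N) stopf("Gamma must be square")
  if (any(Gamma < 0) || any(abs(rowSums(Gamma) - 1) > 1e-8))
    stopf("Gamma is not row-stochastic")
  A <- diag(N) - Gamma + matrix(1, N, N)
  as.numeric(solve(t(A), rep(1, N)))
}
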