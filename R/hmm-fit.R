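#' Construct a movement HMM with known parameters
#'
#' Builds an HMM object from explicit parameter values, usable everywhere a
#' fitted model is ([log_likelihood()], [viterbi()], [pseudo_residuals()],
#' [stationary_profile()]). This is how simulation experiments evaluate the
#' generating model on the same footing as a fitted one.
#'
#' @param step_mean,step_sd gamma step parameters per state (meters, > 0).
#' @param angle_mean,angle_kappa von Mises angle parameters per state.
#' @param beta transition coefficient matrix `(1 + p) x N(N-1)` (see
#'   [transition_matrix()]); `NULL` for N = 1.
#' @param zero_mass optional per-state point mass at step 0 (default none).
#' @param design optional `covariate_design` matching the rows of `beta`
#'   beyond the intercept; `NULL` for an intercept-only transition model.
#' @param delta initial-distribution rule: `"stationary"` (stationary
#'   distribution of the transition matrix at each track's first covariates)
#'   or `"free"` (explicit `delta0`).
#' @param delta0 initial distribution when `delta = "free"`.
#' @return an object of class `hmm_model`.
#' @export
hmm_model <- function(step_mean, step_sd, angle_mean, angle_kappa,
                      beta = NULL, zero_mass = NULL, design = NULL,
                      delta = c("stationary", "free"), delta0 = NULL) {
  delta <- match.arg(delta)
  N <- length(step_mean)
  stopifnot(length(step_sd) == N, length(angle_mean) == N,
            length(angle_kappa) == N)
  if (any(step_mean <= 0) || any(step_sd <= 0))
    stopf("step parameters must be > 0")
  if (any(angle_kappa < 0)) stopf("angle_kappa must be >= 0")
  if (is.null(zero_mass)) zero_mass <- rep(0, N)
  if (any(zero_mass < 0 | zero_mass >= 1))
    stopf("zero_mass must be in [0, 1)")
  p <- if (is.null(design)) 0 else length(design$colnames) - 1
  if (N > 1) {
    beta <- as.matrix(beta)
    if (!all(dim(beta) == c(1 + p, N * (N - 1))))
      stopf("beta must be %d x %d", 1 + p, N * (N - 1))
  } else beta <- matrix(0, 1 + p, 0)
  if (delta == "free") {
    if (is.null(delta0) || length(delta0) != N ||
        abs(sum(delta0) - 1) > 1e-8)
      stopf("delta0 must be a length-%d probability vector", N)
  }
  structure(list(
    n_states = N,
    par = list(step_mean = step_mean, step_sd = step_sd,
               zero_mass = zero_mass,
               angle_mean = wrap_angle(angle_mean),
               angle_kappa = angle_kappa, beta = beta),
    design = design, delta_rule = delta, delta0 = delta0
  ), class = "hmm_model")
}

# shared plumbing: track boundaries and design matrix for C-level calls
hmm_data <- function(model, tracks) {
  stopifnot(nrow(tracks) > 0)
  tid <- paste(tracks$animal_id, tracks$night)
  r <- rle(tid)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  X <- if (is.null(model$design)) matrix(1, nrow(tracks), 1)
       else design_matrix(model$design, tracks)
  list(step = as.numeric(tracks$step), angle = as.numeric(tracks$angle),
       X = X, starts = as.integer(starts), ends = as.integer(ends))
}

#' Forward-algorithm log-likelihood
#'
#' Exact HMM log-likelihood summed over tracks (tracks are independent),
#' computed by the scaled forward recursion. Missing emission channels
#' contribute a factor 1 (so slots with no observations are transition-only
#' steps), and the initial distribution per track follows the model's rule.
#'
#' @param model an `hmm_model` or fitted `hmm_fit`.
#' @param tracks a `track_set` with `step`, `angle` and any covariate
#'   columns the model's design needs.
#' @return the log-likelihood (scalar); `-Inf` with a warning if some track
#'   has zero likelihood.
#' @export
log_likelihood <- function(model, tracks) {
  d <- hmm_data(model, tracks)
  p <- model$par
  ll <- C_hmm_loglik(d$step, d$angle, d$X, d$starts, d$ends,
                     p$step_mean, p$step_sd, p$zero_mass,
                     p$angle_mean, pmax(p$angle_kappa, 1e-8), p$beta,
                     model$delta_rule == "stationary",
                     model$delta0 %||% rep(1 / model$n_states,
                                           model$n_states))
  if (!is.finite(ll))
    warnf("zero likelihood: some observation is impossible under the model")
  ll
}

# ---- working-scale parameterization -------------------------------------

pack_par <- function(p, zm, delta_free, delta0 = NULL) {
  w <- c(log(p$step_mean), log(p$step_sd))
  if (zm) w <- c(w, qlogis(pmin(pmax(p$zero_mass, 1e-6), 1 - 1e-6)))
  w <- c(w, sin(p$angle_mean), cos(p$angle_mean), log(pmax(p$angle_kappa,
                                                           1e-8)))
  w <- c(w, as.numeric(p$beta))
  if (delta_free) w <- c(w, log(delta0[-1] / delta0[1]))
  w
}

unpack_par <- function(w, N, p_cov, zm, delta_free) {
  i <- 0
  take <- function(k) { out <- w[(i + 1):(i + k)]; i <<- i + k; out }
  step_mean <- exp(take(N))
  step_sd <- exp(take(N))
  zero_mass <- if (zm) plogis(take(N)) else rep(0, N)
  s <- take(N); cc <- take(N)
  angle_mean <- ifelse(s == 0 & cc == 0, 0, atan2(s, cc))
  angle_kappa <- pmax(exp(take(N)), 1e-8)
  beta <- matrix(take((1 + p_cov) * N * (N - 1)), nrow = 1 + p_cov)
  delta0 <- NULL
  if (delta_free) {
    e <- exp(c(0, take(N - 1)))
    delta0 <- e / sum(e)
  }
  list(step_mean = step_mean, step_sd = step_sd, zero_mass = zero_mass,
       angle_mean = angle_mean, angle_kappa = angle_kappa, beta = beta,
       delta0 = delta0)
}

# permutation of beta columns when states are relabeled by ord
permute_beta <- function(beta, ord) {
  N <- length(ord)
  if (N < 2) return(beta)
  col_of <- function(i, j) (i - 1) * (N - 1) + j - (j > i)
  out <- beta
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    out[, col_of(i, j)] <- beta[, col_of(ord[i], ord[j])]
  }
  out
}

#' Fit a movement HMM by maximum likelihood
#'
#' Direct numerical maximization of the forward log-likelihood on an
#' unconstrained working scale (log step mean/sd, logit zero mass, angle
#' mean as a (sin, cos) pair to avoid wrap discontinuities, log
#' concentration, unconstrained transition coefficients), using BFGS with
#' multiple starting values: start 1 is moment-based (an N-quantile split of
#' the observed steps), the rest are random perturbations of it. The best
#' converged optimum is kept (ties within 1e-6 log-likelihood units go to
#' the earlier start), and states are relabeled in increasing order of
#' fitted step mean so "state 1" is always the shortest-step state.
#'
#' A point mass at step length exactly 0 is added automatically when the
#' data contain exact zeros (`zero_inflation = NULL`); set `TRUE`/`FALSE` to
#' force.
#'
#' @param tracks a `track_set` with `step`/`angle` columns (see
#'   [build_tracks()]) and any covariate columns used.
#' @param n_states number of latent states.
#' @param numeric_covariates,categorical_covariates covariate columns
#'   entering the transition model (see [build_design()]).
#' @param n_starts number of starting values.
#' @param seed seed for the random perturbations.
#' @param zero_inflation `NULL` (auto), `TRUE` or `FALSE`.
#' @param delta initial-distribution rule, `"stationary"` (default) or
#'   `"free"` (the initial distribution is estimated, adding N-1
#'   parameters).
#' @param se compute standard errors (numerical Hessian + delta method)?
#' @param reference,standardize,merge_rare passed to [build_design()].
#' @param maxit,reltol BFGS control.
#' @param name label used in model tables (default built from covariates).
#' @return an object of classes `hmm_fit` and `hmm_model`, with elements
#'   `par` (natural-scale estimates), `loglik`, `npar`, `aic`,
#'   `convergence`, `starts` (per-start diagnostics), `se` (if requested),
#'   `design`, `checksum`.
#' @export
fit_hmm <- function(tracks, n_states = 3,
                    numeric_covariates = character(),
                    categorical_covariates = character(),
                    n_starts = 25, seed = 1, zero_inflation = NULL,
                    delta = c("stationary", "free"), se = FALSE,
                    reference = list(), standardize = TRUE, merge_rare = 50,
                    maxit = 500, reltol = 1e-9, name = NULL) {
  delta <- match.arg(delta)
  N <- as.integer(n_states)
  steps <- tracks$step
  angles <- tracks$angle
  if (sum(!is.na(steps)) + sum(!is.na(angles)) == 0)
    stopf("no non-missing emissions to fit to")
  zm <- zero_inflation %||% any(steps == 0, na.rm = TRUE)
  if (zm && is.null(zero_inflation))
    message("exact-zero steps present: zero-mass step parameter enabled")
  design <- NULL
  if (length(numeric_covariates) + length(categorical_covariates) > 0)
    design <- build_design(tracks, numeric = numeric_covariates,
                           categorical = categorical_covariates,
                           reference = reference,
                           standardize = standardize,
                           merge_rare = merge_rare)
  p_cov <- if (is.null(design)) 0 else length(design$colnames) - 1
  delta_free <- delta == "free"

  # moment-based start: quantile split of observed positive steps
  s_obs <- steps[!is.na(steps)]
  s_pos <- s_obs[s_obs > 0]
  qs <- quantile(s_pos, probs = seq(0, 1, length.out = N + 1))
  grp <- cut(s_pos, unique(qs), include.lowest = TRUE)
  mu0 <- as.numeric(tapply(s_pos, grp, mean))
  sd0 <- as.numeric(tapply(s_pos, grp, sd))
  if (length(mu0) < N || anyNA(mu0)) {  # fallback for tiny data
    mu0 <- mean(s_pos) * seq(0.5, 1.5, length.out = N)
    sd0 <- rep(sd(s_pos), N)
  }
  sd0 <- pmax(sd0, mu0 * 0.1, 1e-3)
  z0 <- if (zm) rep(min(max(mean(s_obs == 0), 0.01), 0.5), N) else rep(0, N)
  start_par <- list(step_mean = mu0, step_sd = sd0, zero_mass = z0,
                    angle_mean = rep(0, N), angle_kappa = rep(1, N))
  if (N > 1) {
    off <- 0.2 / (N - 1)
    beta0 <- matrix(0, 1 + p_cov, N * (N - 1))
    beta0[1, ] <- log(off / 0.8)
  } else beta0 <- matrix(0, 1 + p_cov, 0)
  start_par$beta <- beta0
  w0 <- pack_par(start_par, zm, delta_free, rep(1 / N, N))
  npar_w <- length(w0)

  d <- hmm_data(list(design = design), tracks)
  unif_delta <- rep(1 / N, N)
  nll <- function(w) {
    if (any(!is.finite(w)) || any(abs(w) > 30))
      return(1e10 + 1e6 * sum(pmax(abs(w[is.finite(w)]) - 30, 0)))
    u <- unpack_par(w, N, p_cov, zm, delta_free)
    ll <- C_hmm_loglik(d$step, d$angle, d$X, d$starts, d$ends,
                       u$step_mean, u$step_sd, u$zero_mass,
                       u$angle_mean, u$angle_kappa, u$beta,
                       !delta_free, u$delta0 %||% unif_delta)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # perturbation scales per working-parameter block
  block_sd <- c(rep(0.4, 2 * N), if (zm) rep(0.5, N),
                rep(0.7, 2 * N), rep(0.6, N),
                rep(c(0.7, rep(0.3, p_cov)), N * (N - 1)),
                if (delta_free) rep(0.5, N - 1))
  starts_w <- with_seed(seed, {
    lapply(seq_len(n_starts), function(s) {
      if (s == 1) w0 else w0 + rnorm(npar_w, 0, block_sd)
    })
  })

  results <- lapply(seq_along(starts_w), function(s) {
    res <- tryCatch(
      optim(starts_w[[s]], nll, method = "BFGS",
            control = list(maxit = maxit, reltol = reltol)),
      error = function(e) list(value = Inf, convergence = 99,
                               message = conditionMessage(e), par = NULL))
    list(start = s, loglik = -res$value,
         converged = identical(res$convergence, 0L) ||
           identical(res$convergence, 0),
         par = res$par)
  })
  diag_df <- data.frame(
    start = vapply(results, `[[`, numeric(1), "start"),
    loglik = vapply(results, `[[`, numeric(1), "loglik"),
    converged = vapply(results, `[[`, logical(1), "converged")
  )
  conv <- Filter(function(r) r$converged && is.finite(r$loglik), results)
  if (length(conv) == 0) {
    print(diag_df)
    stopf("no start converged (%d attempted); per-start diagnostics above",
          n_starts)
  }
  lls <- vapply(conv, `[[`, numeric(1), "loglik")
  best <- conv[[which(lls > max(lls) - 1e-6)[1]]]

  u <- unpack_par(best$par, N, p_cov, zm, delta_free)
  se_out <- NULL
  if (se) {
    H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
    V <- if (!is.null(H))
      tryCatch(solve(H), error = function(e) NULL) else NULL
    if (!is.null(V)) {
      vd <- diag(V)
      vd[vd < 0] <- NA
      # delta method on the log scale: se(exp(w)) = exp(w) * se(w)
      se_out <- list(step_mean = u$step_mean * sqrt(vd[1:N]),
                     step_sd = u$step_sd * sqrt(vd[(N + 1):(2 * N)]))
    }
  }

  ord <- order(u$step_mean)
  fit <- hmm_model(
    step_mean = u$step_mean[ord], step_sd = u$step_sd[ord],
    angle_mean = u$angle_mean[ord], angle_kappa = u$angle_kappa[ord],
    beta = permute_beta(u$beta, ord),
    zero_mass = if (zm) u$zero_mass[ord] else NULL,
    design = design, delta = delta,
    delta0 = if (delta_free) u$delta0[ord] else NULL
  )
  if (!is.null(se_out))
    se_out <- lapply(se_out, function(v) v[ord])

  npar <- N * (2 + as.integer(zm)) + 2 * N +
    (1 + p_cov) * N * (N - 1) + if (delta_free) N - 1 else 0
  fit$loglik <- best$loglik
  fit$npar <- npar
  fit$aic <- -2 * best$loglik + 2 * npar
  fit$convergence <- TRUE
  fit$n_starts <- n_starts
  fit$starts <- diag_df
  fit$se <- se_out
  fit$zero_inflation <- zm
  fit$checksum <- data_checksum(tracks)
  fit$name <- name %||% if (is.null(design)) sprintf("%d-state null", N)
    else paste(c(numeric_covariates, categorical_covariates),
               collapse = " + ")
  class(fit) <- c("hmm_fit", "hmm_model")
  fit
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("Movement HMM fit: %s (%d states)\n", x$name, x$n_states))
  cat(sprintf("log-likelihood %.3f, %d parameters, AIC %.2f\n",
              x$loglik, x$npar, x$aic))
  tab <- data.frame(
    step_mean = x$par$step_mean, step_sd = x$par$step_sd,
    angle_mean = x$par$angle_mean, angle_kappa = x$par$angle_kappa)
  if (x$zero_inflation) tab$zero_mass <- x$par$zero_mass
  print(round(tab, 3))
  invisible(x)
}
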