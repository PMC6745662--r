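#' Viterbi decoding of behavioral states
#'
#' The jointly most probable latent-state path per track under the model's
#' transition matrices and emission densities. Missing emission channels
#' contribute a factor 1; ties are broken toward the lower state index.
#' Slots with missing covariates take the transition at reference covariate
#' values (flagged with a warning).
#'
#' @param model an `hmm_model` or `hmm_fit`.
#' @param tracks a `track_set` carrying the model's covariates.
#' @return `tracks` with an integer `state` column added.
#' @export
viterbi <- function(model, tracks) {
  d <- hmm_data(model, tracks)
  if (!is.null(model$design)) {
    cv <- c(model$design$numeric, model$design$categorical)
    n_na <- sum(!complete.cases(tracks[cv]))
    if (n_na > 0)
      warnf("%d slot(s) with missing covariates use reference covariates",
            n_na)
  }
  p <- model$par
  tracks$state <- C_viterbi(d$step, d$angle, d$X, d$starts, d$ends,
                            p$step_mean, p$step_sd, p$zero_mass,
                            p$angle_mean, pmax(p$angle_kappa, 1e-8), p$beta,
                            model$delta_rule == "stationary",
                            model$delta0 %||% rep(1 / model$n_states,
                                                  model$n_states))
  tracks
}

#' Stationary state probabilities along a covariate gradient
#'
#' For each value on a grid of one covariate (other numeric covariates held
#' at their training means, categoricals at their reference level unless
#' overridden in `held_at`), builds the transition matrix from the fitted
#' coefficients and returns its stationary distribution — the marginal
#' probability of each state at that covariate value.
#'
#' @param fit a fitted `hmm_fit` with a covariate design.
#' @param covariate name of the covariate to profile (raw scale).
#' @param grid numeric grid of covariate values (default: 50 points over
#'   the training range). Values outside the training range are allowed
#'   with an extrapolation warning.
#' @param held_at named list fixing other covariates (raw scale / level).
#' @param group_by optional categorical covariate whose levels each get
#'   their own profile (e.g. `"sex"`).
#' @return a data.frame of class `stationary_profile` with columns
#'   `covariate` (value), `group`, `state`, `prob`.
#' @export
stationary_profile <- function(fit, covariate, grid = NULL,
                               held_at = list(), group_by = NULL) {
  design <- fit$design
  if (is.null(design)) stopf("fit has no covariate design")
  if (!covariate %in% c(design$numeric, design$categorical))
    stopf("covariate '%s' is not in the fit's design", covariate)
  if (is.null(grid)) {
    rg <- design$range[[covariate]]
    grid <- seq(rg[1], rg[2], length.out = 50)
  } else if (!is.null(design$range[[covariate]])) {
    rg <- design$range[[covariate]]
    if (any(grid < rg[1] | grid > rg[2]))
      warnf("profile grid extends beyond the training range of '%s'",
            covariate)
  }
  groups <- if (is.null(group_by)) list(NULL)
            else as.list(design$levels[[group_by]])
  out <- list()
  for (g in groups) {
    for (v in grid) {
      vals <- held_at
      vals[[covariate]] <- v
      if (!is.null(g)) vals[[group_by]] <- g
      x <- design_row(design, vals)
      delta <- stationary(transition_matrix(fit$par$beta, as.numeric(x)))
      out[[length(out) + 1]] <- data.frame(
        covariate = v, group = if (is.null(g)) "all" else g,
        state = seq_len(fit$n_states), prob = delta)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "covariate") <- covariate
  class(res) <- c("stationary_profile", "data.frame")
  res
}

#' One-step-ahead pseudo-residuals
#'
#' Probability-integral-transform residuals: for each slot,
#' `u_t = P(X_t <= x_t | x_{1:t-1})` computed by mixing the per-state
#' emission CDF over the one-step-ahead predictive state weights from the
#' forward recursion (ordinary, forward-only conditioning). Under a
#' correctly specified model the `u` values are standard uniform; `z`
#' values are their standard-normal quantiles. The step channel handles the
#' zero-mass atom by taking the CDF midpoint of the jump; missing channels
#' yield missing residuals. Values of exactly 0 or 1 are clamped to
#' `(1e-12, 1 - 1e-12)`.
#'
#' @inheritParams viterbi
#' @return data.frame with `animal_id`, `night`, `slot`, `u_step`,
#'   `z_step`, `u_angle`, `z_angle`.
#' @export
pseudo_residuals <- function(model, tracks) {
  d <- hmm_data(model, tracks)
  p <- model$par
  N <- model$n_states
  W <- C_forward_weights(d$step, d$angle, d$X, d$starts, d$ends,
                         p$step_mean, p$step_sd, p$zero_mass,
                         p$angle_mean, pmax(p$angle_kappa, 1e-8), p$beta,
                         model$delta_rule == "stationary",
                         model$delta0 %||% rep(1 / N, N))
  shape <- p$step_mean^2 / p$step_sd^2
  scale <- p$step_sd^2 / p$step_mean
  n <- nrow(tracks)
  u_step <- rep(NA_real_, n)
  u_angle <- rep(NA_real_, n)
  ok_s <- !is.na(d$step)
  ok_a <- !is.na(d$angle)
  for (k in seq_len(N)) {
    Fs <- p$zero_mass[k] +
      (1 - p$zero_mass[k]) * pgamma(d$step[ok_s], shape[k], scale = scale[k])
    zero <- d$step[ok_s] == 0
    Fs[zero] <- p$zero_mass[k] / 2     # midpoint of the atom's CDF jump
    u_step[ok_s] <- (if (k == 1) 0 else u_step[ok_s]) + W[ok_s, k] * Fs
    Fa <- pvonmises(d$angle[ok_a], p$angle_mean[k], p$angle_kappa[k])
    u_angle[ok_a] <- (if (k == 1) 0 else u_angle[ok_a]) + W[ok_a, k] * Fa
  }
  clamp <- function(u) pmin(pmax(u, 1e-12), 1 - 1e-12)
  data.frame(
    animal_id = tracks$animal_id, night = tracks$night, slot = tracks$slot,
    u_step = ifelse(ok_s, clamp(u_step), NA),
    z_step = ifelse(ok_s, qnorm(clamp(u_step)), NA),
    u_angle = ifelse(ok_a, clamp(u_angle), NA),
    z_angle = ifelse(ok_a, qnorm(clamp(u_angle)), NA)
  )
}

#' AIC model comparison table
#'
#' Ranks fitted models by AIC with the difference to the best model. Fits
#' must have been estimated on identical track data (checked through a data
#' fingerprint); ties in AIC are ordered by fewer parameters.
#'
#' @param ... fitted `hmm_fit` objects, or a single list of them.
#' @return a data.frame of class `model_table` with columns `model`,
#'   `logLik`, `npar`, `AIC`, `dAIC`, sorted by AIC.
#' @export
model_table <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "hmm_fit"))
    fits <- fits[[1]]
  stopifnot(length(fits) >= 1)
  sums <- lapply(fits, `[[`, "checksum")
  if (length(unique(vapply(sums, paste, character(1), collapse = "|"))) > 1)
    stopf("fits were not estimated on the same track data")
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "name"),
    logLik = vapply(fits, `[[`, numeric(1), "loglik"),
    npar = vapply(fits, `[[`, numeric(1), "npar"),
    AIC = vapply(fits, `[[`, numeric(1), "aic")
  )
  tab <- tab[order(tab$AIC, tab$npar), ]
  tab$dAIC <- tab$AIC - min(tab$AIC)
  rownames(tab) <- NULL
  class(tab) <- c("model_table", "data.frame")
  tab
}

#' Compare candidate numbers of states
#'
#' Fits an HMM for each candidate number of states and reports both
#' selection criteria side by side: AIC (with the within-2 parsimony rule)
#' and pseudo-residual goodness of fit (Kolmogorov-Smirnov statistics per
#' emission channel). AIC tends to favor more states, so the report states
#' both criteria rather than auto-deciding when they conflict.
#'
#' @param tracks a `track_set`.
#' @param candidates integer vector of state counts to try.
#' @param n_starts,seed,... passed to [fit_hmm()].
#' @return a data.frame of class `state_selection` with one row per
#'   candidate (`logLik`, `npar`, `AIC`, `dAIC`, `ks_step`, `ks_angle` and
#'   their p-values), with attributes `fits`, `preferred_aic` (smallest N
#'   within 2 AIC of the best) and `preferred_resid` (N minimizing the
#'   summed KS statistics).
#' @export
select_states <- function(tracks, candidates = c(2, 3), n_starts = 10,
                          seed = 1, ...) {
  fits <- lapply(seq_along(candidates), function(i)
    fit_hmm(tracks, n_states = candidates[i], n_starts = n_starts,
            seed = seed + i, ...))
  ks <- lapply(fits, function(f) {
    r <- pseudo_residuals(f, tracks)
    ks_s <- suppressWarnings(ks.test(r$u_step[!is.na(r$u_step)], "punif"))
    ks_a <- suppressWarnings(ks.test(r$u_angle[!is.na(r$u_angle)], "punif"))
    c(ks_step = unname(ks_s$statistic), ks_step_p = ks_s$p.value,
      ks_angle = unname(ks_a$statistic), ks_angle_p = ks_a$p.value)
  })
  tab <- data.frame(
    n_states = candidates,
    logLik = vapply(fits, `[[`, numeric(1), "loglik"),
    npar = vapply(fits, `[[`, numeric(1), "npar"),
    AIC = vapply(fits, `[[`, numeric(1), "aic"),
    do.call(rbind, ks)
  )
  tab$dAIC <- tab$AIC - min(tab$AIC)
  within2 <- candidates[tab$dAIC <= 2]
  attr(tab, "preferred_aic") <- min(within2)
  attr(tab, "preferred_resid") <-
    candidates[which.min(tab$ks_step + tab$ks_angle)]
  attr(tab, "fits") <- fits
  class(tab) <- c("state_selection", "data.frame")
  tab
}

#' @export
print.state_selection <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("\nAIC (within-2 rule) prefers %d states;",
              attr(x, "preferred_aic")))
  cat(sprintf(" pseudo-residual KS prefers %d states.\n",
              attr(x, "preferred_resid")))
  invisible(x)
}

#' Activity budget from decoded states
#'
#' Share of decoded slots per behavioral state within each group (site,
#' sex, animal, ...). By default only slots with an observed position are
#' counted, matching budgets quoted as proportions of recorded locations.
#'
#' @param tracks a decoded `track_set` (see [viterbi()]) with a `state`
#'   column; may carry grouping columns.
#' @param group_by character vector of grouping columns (empty: one pooled
#'   group).
#' @param only_observed count only slots with an observed position?
#' @return data.frame with the grouping columns, `state`, `n` and `prop`
#'   (proportions sum to 1 within each group).
#' @export
activity_budget <- function(tracks, group_by = character(),
                            only_observed = TRUE) {
  stopifnot("state" %in% names(tracks))
  keep <- !is.na(tracks$state)
  if (only_observed) keep <- keep & !is.na(tracks$x) & !is.na(tracks$y)
  d <- tracks[keep, , drop = FALSE]
  if (nrow(d) == 0) {
    warnf("no decoded slots to summarize")
    return(data.frame(state = integer(), n = integer(), prop = numeric()))
  }
  grp <- if (length(group_by) == 0) rep("all", nrow(d))
         else interaction(d[group_by], drop = TRUE, sep = "/")
  out <- list()
  for (g in levels(factor(grp))) {
    s <- d$state[grp == g]
    tt <- table(factor(s, levels = sort(unique(d$state))))
    df <- data.frame(group = g, state = as.integer(names(tt)),
                     n = as.integer(tt), prop = as.numeric(tt) / sum(tt))
    out[[g]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plot fitted state-dependent distributions
#'
#' Histograms of observed step lengths and turning angles overlaid with the
#' fitted per-state emission densities weighted by the decoded state
#' proportions.
#'
#' @param x a fitted `hmm_fit`.
#' @param tracks the `track_set` the model was fitted to.
#' @param ... unused.
#' @return invisibly, the decoded state proportions used as weights.
#' @export
plot.hmm_fit <- function(x, tracks, ...) {
  dec <- viterbi(x, tracks)
  w <- as.numeric(table(factor(dec$state, levels = seq_len(x$n_states))))
  w <- w / sum(w)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  s <- tracks$step[!is.na(tracks$step)]
  graphics::hist(s, breaks = 50, freq = FALSE, main = "Step length",
                 xlab = "meters", border = "grey")
  sg <- seq(1e-3, max(s), length.out = 300)
  for (k in seq_len(x$n_states))
    graphics::lines(sg, w[k] * gamma_step_density(
      sg, x$par$step_mean[k], x$par$step_sd[k], x$par$zero_mass[k]),
      col = k + 1, lwd = 2)
  a <- tracks$angle[!is.na(tracks$angle)]
  graphics::hist(a, breaks = 40, freq = FALSE, main = "Turning angle",
                 xlab = "radians", border = "grey")
  ag <- seq(-pi, pi, length.out = 300)
  for (k in seq_len(x$n_states))
    graphics::lines(ag, w[k] * vonmises_density(
      ag, x$par$angle_mean[k], x$par$angle_kappa[k]), col = k + 1, lwd = 2)
  invisible(w)
}
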