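# Independent oracles used across tests. These deliberately avoid the
# package's C++ recursions: transition matrices by plain softmax, stationary
# distributions by eigendecomposition, likelihood/decoding by exhaustive
# path enumeration, Bessel I0 by power series.

oracle_gamma <- function(beta, x) {
  m <- ncol(beta)
  N <- as.integer((1 + sqrt(1 + 4 * m)) / 2)
  if (length(x) == nrow(beta) - 1) x <- c(1, x)
  G <- matrix(0, N, N)
  idx <- 0
  eta <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    idx <- idx + 1
    eta[i, j] <- sum(beta[, idx] * x)
  }
  for (i in seq_len(N)) G[i, ] <- exp(eta[i, ]) / sum(exp(eta[i, ]))
  G
}

oracle_stationary <- function(G) {
  e <- eigen(t(G))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

oracle_i0 <- function(kappa, terms = 80) {
  m <- 0:terms
  sum((kappa^2 / 4)^m / factorial(m)^2)
}

# per-slot emission likelihood under a model, missing channels = factor 1
oracle_emission <- function(model, step, angle) {
  p <- model$par
  N <- model$n_states
  E <- matrix(1, length(step), N)
  for (k in seq_len(N)) {
    es <- ifelse(is.na(step), 1,
                 gamma_step_density(ifelse(is.na(step), 1, step),
                                    p$step_mean[k], p$step_sd[k],
                                    p$zero_mass[k]))
    ea <- ifelse(is.na(angle), 1,
                 vonmises_density(angle, p$angle_mean[k], p$angle_kappa[k]))
    E[, k] <- es * ea
  }
  E
}

# exhaustive-path log-likelihood for a single track
oracle_track_loglik <- function(model, step, angle, X) {
  N <- model$n_states
  T_ <- length(step)
  E <- oracle_emission(model, step, angle)
  Gs <- lapply(seq_len(T_), function(t) oracle_gamma(model$par$beta, X[t, ]))
  delta <- if (model$delta_rule == "stationary")
    oracle_stationary(Gs[[1]]) else model$delta0
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), T_)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- delta[s[1]] * E[1, s[1]]
    for (t in seq_len(T_)[-1])
      pr <- pr * Gs[[t - 1]][s[t - 1], s[t]] * E[t, s[t]]
    tot <- tot + pr
  }
  log(tot)
}

oracle_loglik <- function(model, tracks) {
  X <- if (is.null(model$design)) matrix(1, nrow(tracks), 1)
       else design_matrix(model$design, tracks)
  tid <- paste(tracks$animal_id, tracks$night)
  sum(vapply(unique(tid), function(id) {
    i <- tid == id
    oracle_track_loglik(model, tracks$step[i], tracks$angle[i],
                        X[i, , drop = FALSE])
  }, numeric(1)))
}

# exhaustive-path Viterbi with lexicographic tie-break toward lower states
oracle_viterbi <- function(model, step, angle, X) {
  N <- model$n_states
  T_ <- length(step)
  E <- oracle_emission(model, step, angle)
  Gs <- lapply(seq_len(T_), function(t) oracle_gamma(model$par$beta, X[t, ]))
  delta <- if (model$delta_rule == "stationary")
    oracle_stationary(Gs[[1]]) else model$delta0
  grid_args <- rev(rep(list(seq_len(N)), T_))
  paths <- as.matrix(expand.grid(grid_args))[, T_:1, drop = FALSE]
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(paths))) {   # rows come in lexicographic order
    s <- paths[r, ]
    lp <- log(delta[s[1]]) + log(E[1, s[1]])
    for (t in seq_len(T_)[-1])
      lp <- lp + log(Gs[[t - 1]][s[t - 1], s[t]]) + log(E[t, s[t]])
    if (lp > best + 1e-12) { best <- lp; best_path <- s }
  }
  best_path
}

# random small HMM instance (tracks + model) for oracle-equivalence checks
random_instance <- function(N, T_, with_covariate = FALSE,
                            with_missing = TRUE) {
  tracks <- data.frame(
    animal_id = "A1", night = as.Date("2016-06-01"), slot = seq_len(T_),
    x = 0, y = 0,
    step = rgamma(T_, 2, 0.05), angle = wrap_angle(runif(T_, -pi, pi))
  )
  tracks$step[1] <- NA; tracks$angle[1] <- NA
  if (T_ > 1) tracks$angle[2] <- NA
  if (with_missing && T_ > 3) {
    tracks$step[sample(3:T_, 1)] <- NA
    tracks$angle[sample(3:T_, 1)] <- NA
  }
  design <- NULL
  p <- 0
  if (with_covariate) {
    tracks$cov1 <- rnorm(T_)
    design <- build_design(tracks, numeric = "cov1", merge_rare = 0)
    p <- 1
  }
  mu <- sort(rgamma(N, 4, 0.08)) + 5
  model <- hmm_model(
    step_mean = mu, step_sd = mu * runif(N, 0.4, 1.2),
    angle_mean = wrap_angle(runif(N, -pi, pi)),
    angle_kappa = runif(N, 0, 3),
    beta = if (N > 1) matrix(rnorm((1 + p) * N * (N - 1), 0, 0.8),
                             1 + p, N * (N - 1)) else NULL,
    design = design
  )
  list(model = model, tracks = tracks)
}

# small simulated data set shared by several test files (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ls <- simulate_landscape(landscape_config(grid_size = 150,
                                                resolution = 30,
                                                n_patches = 6, seed = 21))
      ls <- derive_covariate_layers(ls, K = 5, seed = 22)
      mod <- true_model(gps_error_sd = 0, missing_prob = 0.05)
      sim <- simulate_tracks(mod, ls, n_animals = 4, n_nights = 4,
                             seed = 23)
      tr <- attach_covariates(build_tracks(sim$fixes), ls)
      cache <<- list(landscape = ls, model = mod, sim = sim, tracks = tr)
    }
    cache
  }
})
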