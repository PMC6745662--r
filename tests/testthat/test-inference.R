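# Decoding, stationary profiles, pseudo-residuals, model tables, budgets.

test_that("Viterbi matches exhaustive path maximization", {
  set.seed(61)
  for (r in 1:25) {
    N <- sample(2:3, 1)
    T_ <- sample(3:7, 1)
    inst <- random_instance(N, T_, with_covariate = r %% 2 == 0)
    dec <- viterbi(inst$model, inst$tracks)
    ref <- oracle_viterbi(inst$model, inst$tracks$step, inst$tracks$angle,
                          if (is.null(inst$model$design))
                            matrix(1, T_, 1)
                          else design_matrix(inst$model$design, inst$tracks))
    expect_equal(dec$state, unname(ref))
  }
  # N = 1: everything decodes to state 1
  inst <- random_instance(1, 6)
  expect_true(all(viterbi(inst$model, inst$tracks)$state == 1))
})

test_that("decoding recovers well-separated simulated states", {
  ls <- simulate_landscape(landscape_config(grid_size = 250, seed = 62))
  # well-separated states: distinct step scales plus high angle
  # concentrations
  gen <- true_model(angle_kappa = c(2, 2, 5), persistence = 0.85,
                    gps_error_sd = 0, missing_prob = 0)
  sim <- simulate_tracks(gen, ls, n_animals = 8, n_nights = 3, seed = 63)
  tr <- build_tracks(sim$fixes)
  gm <- hmm_model(step_mean = gen$step_mean, step_sd = gen$step_sd,
                  angle_mean = gen$angle_mean, angle_kappa = gen$angle_kappa,
                  beta = gen$beta)
  dec <- viterbi(gm, tr)
  agree <- mean(dec$state == sim$states$state)
  expect_gte(agree, 0.9)
  # decoded activity budget within 0.05 of the true-state budget
  bud_dec <- activity_budget(dec)
  bud_true <- as.numeric(table(sim$states$state)) / nrow(sim$states)
  expect_lt(max(abs(bud_dec$prop - bud_true)), 0.05)
})

test_that("stationary profiles respond to covariates as the generator does", {
  # woodland mosaic so both ends of the canopy gradient are well sampled
  ls <- simulate_landscape(landscape_config(grid_size = 250, n_patches = 25,
                                            patch_radius_range = c(300, 700),
                                            seed = 64))
  ls <- derive_covariate_layers(ls, K = 5, seed = 65)
  gen <- true_model(covariates = "canopy", gps_error_sd = 0,
                    missing_prob = 0.05)
  sim <- simulate_tracks(gen, ls, n_animals = 12, n_nights = 8, seed = 66)
  tr <- attach_covariates(build_tracks(sim$fixes), ls)
  fit <- fit_hmm(tr, n_states = 3, numeric_covariates = "canopy_pct",
                 n_starts = 4, seed = 67)
  prof <- stationary_profile(fit, "canopy_pct")
  grid <- unique(prof$covariate)
  # probabilities sum to 1 at every grid point
  sums <- tapply(prof$prob, prof$covariate, sum)
  expect_equal(unname(as.numeric(sums)), rep(1, length(grid)),
               tolerance = 1e-12)
  # recovered curves follow the generating model (canopy fraction scale in
  # the generator): same direction of response per state, and close at
  # this moderate sample size
  p2 <- prof$prob[prof$state == 2]
  expect_gt(p2[length(grid)], p2[1])           # foraging rises with canopy
  p1 <- prof$prob[prof$state == 1]
  expect_lt(p1[length(grid)], p1[1])
  for (g in grid) {
    d_true <- oracle_stationary(oracle_gamma(gen$beta, g / 100))
    d_fit <- prof$prob[prof$covariate == g]
    expect_lt(max(abs(d_fit - d_true)), 0.12)
  }
  # grid values outside the training range are flagged
  expect_warning(
    prof0 <- stationary_profile(fit, "canopy_pct", grid = c(-10, 200)),
    "training range")
})

test_that("pseudo-residuals are calibrated under the true model", {
  # N = 1: u equals the plain emission CDF
  set.seed(71)
  inst <- random_instance(1, 8, with_missing = FALSE)
  r <- pseudo_residuals(inst$model, inst$tracks)
  p <- inst$model$par
  ok <- !is.na(inst$tracks$step)
  expect_equal(r$u_step[ok],
               pgamma(inst$tracks$step[ok], p$step_mean^2 / p$step_sd^2,
                      scale = p$step_sd^2 / p$step_mean), tolerance = 1e-9)
  ok <- !is.na(inst$tracks$angle)
  expect_equal(r$u_angle[ok],
               pvonmises(inst$tracks$angle[ok], p$angle_mean,
                         p$angle_kappa), tolerance = 1e-9)
  # under the generating 3-state model, step residuals pass KS uniformity
  ls <- simulate_landscape(landscape_config(grid_size = 250, seed = 72))
  gen <- true_model(gps_error_sd = 0, missing_prob = 0.05)
  gm <- hmm_model(step_mean = gen$step_mean, step_sd = gen$step_sd,
                  angle_mean = gen$angle_mean, angle_kappa = gen$angle_kappa,
                  beta = gen$beta)
  sim <- simulate_tracks(gen, ls, n_animals = 6, n_nights = 3, seed = 73)
  tr <- build_tracks(sim$fixes)
  r <- pseudo_residuals(gm, tr)
  ks <- ks.test(r$u_step[!is.na(r$u_step)], "punif")
  expect_gt(ks$p.value, 0.01)
  ks <- ks.test(r$u_angle[!is.na(r$u_angle)], "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("model tables rank by AIC and refuse mismatched data", {
  s <- small_sim()
  tr <- s$tracks
  f0 <- fit_hmm(tr, n_states = 2, n_starts = 2, seed = 81)
  tab <- model_table(f0)
  expect_equal(tab$dAIC, 0)
  # synthetic second fit: same data, worse logLik but fewer parameters
  f1 <- f0
  f1$loglik <- f0$loglik - 1
  f1$npar <- f0$npar - 1
  f1$aic <- -2 * f1$loglik + 2 * f1$npar
  f1$name <- "smaller"
  tab <- model_table(f0, f1)
  expect_equal(tab$dAIC[1], 0)
  expect_true(all(diff(tab$AIC) >= 0))
  # exact AIC ties order by fewer parameters
  f2 <- f0
  f2$loglik <- f0$loglik - 1   # AIC identical to f0 with one fewer par
  f2$npar <- f0$npar - 1
  f2$aic <- f0$aic
  f2$name <- "tied"
  tab <- model_table(f0, f2)
  expect_equal(tab$model[1], "tied")
  # different data: checksum mismatch errors
  f3 <- fit_hmm(tr[tr$animal_id != "A01", ], n_states = 2, n_starts = 2,
                seed = 81)
  expect_error(model_table(f0, f3), "same track data")
})

test_that("activity budgets are per-group proportions of decoded slots", {
  d <- data.frame(animal_id = "A", night = 1, slot = 1:4,
                  x = 1, y = 1, state = c(2, 2, 3, 2))
  b <- activity_budget(d)
  expect_equal(b$prop[b$state == 2], 0.75)
  expect_equal(b$prop[b$state == 3], 0.25)
  # grouped: proportions sum to 1 within each group
  d2 <- data.frame(animal_id = rep(c("A", "B"), each = 6), night = 1,
                   slot = 1:6, x = 1, y = 1,
                   state = c(1, 1, 2, 3, 3, 3, 2, 2, 2, 1, 3, 2),
                   sex = rep(c("F", "M"), each = 6))
  b2 <- activity_budget(d2, group_by = "sex")
  sums <- tapply(b2$prop, b2$group, sum)
  expect_equal(unname(as.numeric(sums)), c(1, 1))
  # slots without an observed position are excluded by default
  d$x[1] <- NA
  b3 <- activity_budget(d)
  expect_equal(b3$n[b3$state == 2], 2)
})
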