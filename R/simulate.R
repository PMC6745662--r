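#' Generating model for synthetic movement tracks
#'
#' The "true" movement model the synthetic-track generator runs forward: N
#' latent behavioral states with gamma step-length and von Mises
#' turning-angle emissions, and a multinomial-logit transition matrix driven
#' by habitat covariates sampled along the path. Defaults are set to the
#' study conditions the package emulates: three states with step means
#' 28/103/268 m per 15-min interval (short tortuous denning movements,
#' intermediate foraging, long directed fast-traveling), GPS error of
#' +/- 20 m, and roughly 10% missed fixes.
#'
#' Recognized covariate names and their generator-side scales:
#' `"canopy"` (canopy_pct / 100, in 0-1), `"veg_density"` (NDVI, about 0-1),
#' `"dist_edge"` (distance to woodland per 100 m), `"sexM"` (indicator).
#'
#' @param n_states number of latent states.
#' @param step_mean,step_sd gamma mean and sd per state, meters (> 0).
#' @param angle_mean von Mises mean per state, radians in `(-pi, pi]`.
#' @param angle_kappa von Mises concentration per state (>= 0).
#' @param covariates character vector of transition covariates (may be
#'   empty).
#' @param beta transition coefficient matrix, `(1 + p) x N(N-1)` with the
#'   column ordering of [transition_matrix()]. `NULL` builds a default:
#'   intercepts giving `persistence` on the diagonal, plus moderate effects
#'   for any requested covariates (canopy favors switches into state 2,
#'   vegetation density into state 1, distance-to-edge and male sex into
#'   state N).
#' @param persistence diagonal transition probability used for the default
#'   intercepts.
#' @param gps_error_sd per-coordinate Gaussian location error sd, meters.
#' @param missing_prob probability a fix is missed, in `[0, 1)`.
#' @return an object of class `true_model`.
#' @export
true_model <- function(n_states = 3,
                       step_mean = c(28, 103, 268),
                       step_sd = c(25, 70, 160),
                       angle_mean = c(pi, 0, 0),
                       angle_kappa = c(0.4, 0.6, 2.5),
                       covariates = character(),
                       beta = NULL, persistence = 0.85,
                       gps_error_sd = 20, missing_prob = 0.1) {
  N <- as.integer(n_states)
  if (N < 1) stopf("n_states must be >= 1")
  stopifnot(length(step_mean) == N, length(step_sd) == N,
            length(angle_mean) == N, length(angle_kappa) == N)
  if (any(step_mean <= 0) || any(step_sd <= 0))
    stopf("step_mean and step_sd must be strictly positive")
  if (any(angle_kappa < 0)) stopf("angle_kappa must be >= 0")
  if (missing_prob < 0 || missing_prob >= 1)
    stopf("missing_prob must be in [0, 1)")
  p <- length(covariates)
  if (is.null(beta) && N > 1) {
    off <- (1 - persistence) / (N - 1)
    beta <- matrix(0, 1 + p, N * (N - 1))
    beta[1, ] <- log(off / persistence)
    if (p > 0) {
      target <- c(canopy = 2L, veg_density = 1L, dist_edge = N, sexM = N)
      weight <- c(canopy = 2.0, veg_density = 2.0, dist_edge = 0.3,
                  sexM = 0.8)
      for (ci in seq_along(covariates)) {
        cv <- covariates[ci]
        if (!cv %in% names(target))
          stopf("no default effect for covariate '%s'; supply beta", cv)
        idx <- 0
        for (i in seq_len(N)) for (j in seq_len(N)) {
          if (i == j) next
          idx <- idx + 1
          if (j == target[cv]) beta[1 + ci, idx] <- weight[cv]
        }
      }
    }
  }
  if (N > 1) {
    beta <- as.matrix(beta)
    if (!all(dim(beta) == c(1 + p, N * (N - 1))))
      stopf("beta must be (1+p) x N(N-1) = %d x %d", 1 + p, N * (N - 1))
    if (any(!is.finite(beta))) stopf("beta must be finite")
  } else beta <- matrix(0, 1 + p, 0)
  structure(list(
    n_states = N, step_mean = step_mean, step_sd = step_sd,
    angle_mean = wrap_angle(angle_mean), angle_kappa = angle_kappa,
    covariates = covariates, beta = beta,
    gps_error_sd = gps_error_sd, missing_prob = missing_prob
  ), class = "true_model")
}

# generator-side covariate vector at a position (see ?true_model for scales)
model_covariates <- function(model, landscape, x, y, sexM) {
  if (length(model$covariates) == 0) return(numeric(0))
  # clamp to the nearest cell so covariates stay defined at the boundary
  ext <- c(landscape$nx, landscape$ny) * landscape$resolution
  x <- pmin(pmax(x, landscape$origin[1] + 1e-9),
            landscape$origin[1] + ext[1] - 1e-9)
  y <- pmin(pmax(y, landscape$origin[2] + 1e-9),
            landscape$origin[2] + ext[2] - 1e-9)
  vapply(model$covariates, function(cv) {
    switch(cv,
      canopy = raster_extract(landscape, "canopy_pct", x, y) / 100,
      veg_density = raster_extract(landscape, "ndvi", x, y),
      dist_edge = raster_extract(landscape, "dist_edge", x, y) / 100,
      sexM = as.numeric(sexM),
      stopf("unknown covariate '%s'", cv))
  }, numeric(1))
}

#' Simulate state-switching movement tracks over a landscape
#'
#' Runs a [true_model()] forward over a simulated landscape, emulating the
#' nightly GPS tracking design: per animal and night, 57 slots on the
#' 15-minute grid from 16:00 to 06:00. The latent state evolves by the
#' covariate-dependent transition matrix evaluated at the position of the
#' previous slot (the decision precedes the move); the step is drawn from
#' the state's gamma, the turning angle from its von Mises, and the position
#' updated by dead reckoning (`bearing_t = bearing_{t-1} + angle_t`).
#' Independent Gaussian noise of sd `gps_error_sd` is added per coordinate,
#' and each fix is independently dropped with probability `missing_prob`.
#'
#' Each night starts at the animal's den (its fixed starting position;
#' these animals den by day, so nightly excursions begin and are anchored
#' there), with the state drawn from the stationary distribution at that
#' position and a fresh uniform initial bearing (nightly tracks are treated
#' as independent downstream). Set `return_to_den = FALSE` to let each
#' night continue from the previous night's last position instead. Steps
#' that would leave the landscape are redrawn (up to 100 times, then the
#' position is reflected back inside; the returned object counts
#' reflections).
#'
#' @param model a [true_model()].
#' @param landscape a [landscape_raster()]; must carry the layers needed by
#'   `model$covariates` (see [derive_covariate_layers()]).
#' @param n_animals,n_nights numbers of animals and of nights per animal.
#' @param seed integer seed; output is reproducible bit-for-bit.
#' @param sex character vector of length `n_animals` (`"M"`/`"F"`); default
#'   assigns males and females in about a 14:12 ratio.
#' @param start_date date of the first night.
#' @param return_to_den restart each night at the den?
#' @return a list of class `sim_tracks` with `fixes` (observed fix table:
#'   `animal_id`, `sex`, `timestamp`, `x`, `y`; dropped fixes are absent)
#'   and `states` (one row per slot: true state, true coordinates, drawn
#'   step/angle, and whether the fix was observed), plus `n_reflect`.
#' @export
simulate_tracks <- function(model, landscape, n_animals = 26, n_nights = 18,
                            seed = 1, sex = NULL,
                            start_date = "2016-06-01",
                            return_to_den = TRUE) {
  stopifnot(inherits(model, "true_model"),
            inherits(landscape, "landscape_raster"))
  if (any(model$angle_kappa < 0)) stopf("kappa must be >= 0")
  N <- model$n_states
  n_slots <- 57L
  res <- landscape$resolution
  xmin <- landscape$origin[1]; ymin <- landscape$origin[2]
  xmax <- xmin + landscape$nx * res; ymax <- ymin + landscape$ny * res
  base_epoch <- as.numeric(as.POSIXct(paste(start_date, "16:00:00"),
                                      tz = "UTC"))
  if (is.null(sex)) {
    nM <- round(n_animals * 14 / 26)
    sex <- c(rep("M", nM), rep("F", n_animals - nM))
  }
  stopifnot(length(sex) == n_animals)
  covfree <- length(model$covariates) == 0
  need_dist <- "dist_edge" %in% model$covariates
  if (need_dist && is.null(landscape$layers$dist_edge))
    stopf("model uses dist_edge; run derive_covariate_layers() first")
  if ("veg_density" %in% model$covariates &&
      is.null(landscape$layers$ndvi))
    stopf("model uses veg_density; run derive_covariate_layers() first")

  with_seed(seed, {
    # starting dens: random woodland cell centers
    wood <- which(landscape$layers$woodland_mask != 0, arr.ind = TRUE)
    if (nrow(wood) == 0)
      wood <- cbind(ceiling(landscape$nx / 2), ceiling(landscape$ny / 2))
    pick <- wood[sample.int(nrow(wood), n_animals, replace = TRUE), ,
                 drop = FALSE]
    starts <- cell_center(landscape, pick[, 1], pick[, 2])

    gamma_at_pos <- function(x, y, sm) {
      cv <- model_covariates(model, landscape, x, y, sm)
      transition_matrix(model$beta, cv)
    }
    G0 <- if (covfree && N > 1) transition_matrix(model$beta) else NULL

    n_reflect <- 0L
    st_rows <- vector("list", n_animals * n_nights)
    row_i <- 0
    for (a in seq_len(n_animals)) {
      sm <- sex[a] == "M"
      pos <- starts[a, ]
      for (ng in seq_len(n_nights)) {
        if (return_to_den) pos <- starts[a, ]
        state <- integer(n_slots)
        tx <- numeric(n_slots); ty <- numeric(n_slots)
        s_true <- rep(NA_real_, n_slots); a_true <- rep(NA_real_, n_slots)
        G <- if (covfree) G0 else gamma_at_pos(pos[1], pos[2], sm)
        state[1] <- if (N == 1) 1L else
          sample.int(N, 1, prob = stationary(G))
        tx[1] <- pos[1]; ty[1] <- pos[2]
        bearing <- runif(1, -pi, pi)
        # pre-draw emissions for every state (vectorized), select by path
        Sdraw <- matrix(rgamma((n_slots - 1) * N,
                               shape = model$step_mean^2 / model$step_sd^2,
                               scale = rep(model$step_sd^2 / model$step_mean,
                                           n_slots - 1)),
                        nrow = N)
        Adraw <- t(vapply(seq_len(N), function(k)
          rvonmises(n_slots - 1, model$angle_mean[k], model$angle_kappa[k]),
          numeric(n_slots - 1)))
        for (t in 2:n_slots) {
          if (N > 1) {
            if (!covfree) G <- gamma_at_pos(tx[t - 1], ty[t - 1], sm)
            state[t] <- sample.int(N, 1, prob = G[state[t - 1], ])
          } else state[t] <- 1L
          stp <- Sdraw[state[t], t - 1]
          ang <- Adraw[state[t], t - 1]
          nb <- bearing + ang
          cx <- tx[t - 1] + stp * cos(nb)
          cy <- ty[t - 1] + stp * sin(nb)
          tries <- 0
          while ((cx < xmin || cx > xmax || cy < ymin || cy > ymax) &&
                 tries < 100) {
            stp <- rgamma(1, shape = model$step_mean[state[t]]^2 /
                            model$step_sd[state[t]]^2,
                          scale = model$step_sd[state[t]]^2 /
                            model$step_mean[state[t]])
            ang <- rvonmises(1, model$angle_mean[state[t]],
                             model$angle_kappa[state[t]])
            nb <- bearing + ang
            cx <- tx[t - 1] + stp * cos(nb)
            cy <- ty[t - 1] + stp * sin(nb)
            tries <- tries + 1
          }
          if (cx < xmin || cx > xmax || cy < ymin || cy > ymax) {
            n_reflect <- n_reflect + 1L
            if (cx < xmin) cx <- 2 * xmin - cx
            if (cx > xmax) cx <- 2 * xmax - cx
            if (cy < ymin) cy <- 2 * ymin - cy
            if (cy > ymax) cy <- 2 * ymax - cy
          }
          tx[t] <- cx; ty[t] <- cy
          s_true[t] <- stp; a_true[t] <- ang
          bearing <- nb
        }
        pos <- c(tx[n_slots], ty[n_slots])
        obs_x <- tx + rnorm(n_slots, 0, model$gps_error_sd)
        obs_y <- ty + rnorm(n_slots, 0, model$gps_error_sd)
        observed <- runif(n_slots) >= model$missing_prob
        row_i <- row_i + 1
        st_rows[[row_i]] <- data.frame(
          animal_id = sprintf("A%02d", a), sex = sex[a], night = ng,
          slot = seq_len(n_slots),
          timestamp = as.POSIXct(base_epoch + (ng - 1) * 86400 +
                                   (seq_len(n_slots) - 1) * 900,
                                 origin = "1970-01-01", tz = "UTC"),
          state = state, true_x = tx, true_y = ty,
          step_true = s_true, angle_true = a_true,
          obs_x = obs_x, obs_y = obs_y, observed = observed,
          stringsAsFactors = FALSE
        )
      }
    }
    states <- do.call(rbind, st_rows)
    fx <- states[states$observed,
                 c("animal_id", "sex", "timestamp", "obs_x", "obs_y")]
    names(fx)[4:5] <- c("x", "y")
    rownames(fx) <- NULL
    structure(list(fixes = fx, states = states, model = model,
                   n_reflect = n_reflect), class = "sim_tracks")
  })
}
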