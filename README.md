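# movestate

Hidden Markov models for behavioral states in nightly GPS movement tracks.

`movestate` is for movement ecologists who track nocturnal animals with GPS
collars on a fixed nightly schedule and want to (a) classify relocations
into latent behavioral states — denning, foraging, fast-traveling — from
step lengths and turning angles, and (b) learn how habitat structure drives
switching between those states. It reimplements that full analysis as a
tested pipeline: track regularization, habitat covariate layers (NDVI,
K-means vegetation-density classes, distance to woodland edge, canopy
cover), maximum-likelihood HMM fitting, Viterbi decoding, pseudo-residual
diagnostics, AIC model tables, and stationary-distribution covariate
profiles — plus a synthetic landscape-and-track generator with known
parameters, so every stage is testable without any field data.

## The model

Each animal-night is one track: 57 slots on a 15-minute grid from 16:00 to
06:00, with missing fixes coded as `NA`. Per slot the observations are the
step length $l_t$ (m) and turning angle $\varphi_t \in (-\pi,\pi]$.
Conditional on a latent state $S_t = k$ out of $N$:

$$l_t \sim \mathrm{Gamma}\!\left(\tfrac{\mu_k^2}{\sigma_k^2},\,
\tfrac{\sigma_k^2}{\mu_k}\right) \;(+\ \text{optional point mass at } 0),
\qquad
\varphi_t \sim \mathrm{vonMises}(\mu^a_k, \kappa_k),$$

and the states evolve as a Markov chain whose transition matrix
$\Gamma(x_t)$ depends on habitat covariates through a multinomial logit,
$\gamma_{ij}(x) \propto \exp(\beta_{0,ij} + \beta_{ij}^\top x)$ with
$\gamma_{ii}$ as reference. Tracks are independent; each starts from the
stationary distribution $\delta(x_1)$ of its first transition matrix. The
likelihood is computed exactly by the scaled forward algorithm (missing
channels contribute a factor 1) and maximized from many starting values;
fitted states are always ordered by increasing step mean. Long-run habitat
effects are summarized by stationary profiles: the solution of
$\delta \Gamma(x) = \delta$ swept along one covariate. See the vignette
(`vignettes/movement-hmm.Rmd`) for conventions, numerical choices, and
what the synthetic generator does and does not emulate.

## Worked example

Simulate a fragmented landscape and a small tracking campaign whose
transitions respond to canopy cover and sex, then fit and interrogate the
model (about four minutes, most of it the 8-start fit):

```r
library(movestate)

ls  <- simulate_landscape(landscape_config(grid_size = 200, resolution = 30,
                                           n_patches = 8, seed = 1))
ls  <- derive_covariate_layers(ls, K = 8, seed = 1)
gen <- true_model(covariates = c("canopy", "sexM"))      # study defaults
sim <- simulate_tracks(gen, ls, n_animals = 12, n_nights = 10, seed = 1)

fixes  <- filter_fixes(sim$fixes, drop_first_last_night = FALSE)
tracks <- attach_covariates(build_tracks(fixes), ls)
fit    <- fit_hmm(tracks, n_states = 3,
                  numeric_covariates = "canopy_pct",
                  categorical_covariates = "sex",
                  n_starts = 8, seed = 2)
print(fit)
#> Movement HMM fit: canopy_pct + sex (3 states)
#> log-likelihood -39802.496, 30 parameters, AIC 79664.99
#>   step_mean step_sd angle_mean angle_kappa
#> 1    46.407  27.315      3.059       0.523
#> 2   111.377  76.985     -0.115       0.122
#> 3   262.193 157.486     -0.032       2.046
```

The three states separate cleanly: short tortuous steps (state 1, mean
46 m — inflated above the generating 28 m because the simulated collars
carry ±20 m location error, exactly the caveat that applies to real
denning estimates), intermediate foraging steps, and long directed travel
(262 m, high concentration). Decoding and activity budgets:

```r
decoded <- viterbi(fit, tracks)
activity_budget(decoded, group_by = "sex")
#>   group state    n      prop
#> 1     F     1  950 0.3104575
#> 2     F     2 1361 0.4447712
#> 3     F     3  749 0.2447712
#> 4     M     1  590 0.1910003
#> 5     M     2  890 0.2881191
#> 6     M     3 1609 0.5208805
```

Males fast-travel far more than females (52% vs 24% of locations) — the
generator's sex effect, recovered from the decoded states. Stationary
profiles show the long-run canopy response (female panel):

```r
prof <- stationary_profile(fit, "canopy_pct", grid = c(20, 50, 80),
                           group_by = "sex")
#>         canopy 20% canopy 50% canopy 80%
#> state 1      0.317      0.290      0.255
#> state 2      0.425      0.484      0.539
#> state 3      0.258      0.225      0.206
```

Foraging (state 2) gains probability with canopy cover while denning and
fast-traveling recede, mirroring the direction of the generating model's
canopy effect.

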