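---
title: "Behavioral-state HMMs for nightly GPS tracks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral-state HMMs for nightly GPS tracks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(movestate)
```

## The model

`movestate` classifies regular-interval GPS relocations of nocturnally
active animals into latent behavioral states and relates state switching to
habitat structure. Each night of tracking is treated as one time series of
positions on a 15-minute grid from 16:00 to 06:00 (57 slots). From the
positions we derive, per slot $t$, a step length $l_t$ (meters moved into
slot $t$) and a turning angle $\varphi_t \in (-\pi, \pi]$ (change of bearing,
counterclockwise positive). These two channels are the observations of a
hidden Markov model with $N$ states:

* **State-dependent distributions.** Given state $k$, $l_t$ is gamma with
  mean $\mu_k$ and standard deviation $\sigma_k$ (shape $\mu_k^2/\sigma_k^2$,
  scale $\sigma_k^2/\mu_k$), optionally inflated with a point mass
  $\pi_{0,k}$ at exactly zero; $\varphi_t$ is von Mises with mean direction
  $\mu^a_k$ and concentration $\kappa_k$. Channels are conditionally
  independent given the state. Short tortuous movements (low $\mu$, low
  $\kappa$, mean direction near $\pi$) read as denning, intermediate steps
  as foraging, and long directed steps ($\mu^a \approx 0$, high $\kappa$)
  as fast-traveling.
* **Covariate-dependent transitions.** Switching follows a multinomial
  logit: $\gamma_{ij}(x) = \exp(\eta_{ij}) / \sum_k \exp(\eta_{ik})$ with
  $\eta_{ii} = 0$ and $\eta_{ij} = \beta_{0,ij} + \beta_{ij}^\top x_t$ for
  $i \ne j$. The covariate vector $x_t$ holds habitat attributes sampled at
  the animal's position — percent canopy cover, vegetation-density class,
  distance to woodland edge — plus individual attributes such as sex.
  Categorical covariates enter as $K-1$ indicators against a reference
  level; numeric covariates are z-standardized before fitting (an
  optimizer-conditioning choice; profiles and predictions transform back
  automatically).
* **Initial distribution.** By default each nightly track starts from the
  stationary distribution of its first transition matrix,
  $\delta(x_1) \Gamma(x_1) = \delta(x_1)$; a freely estimated $\delta$
  (adding $N-1$ parameters) is available via `delta = "free"`.

The likelihood is the product over tracks (individuals' tracks are treated
as independent) of the forward recursion, computed with per-step rescaling
and the scale factors accumulated in log space. Missing emission channels
contribute a factor 1, so slots without a usable step or angle are
transition-only; a slot whose position was never recorded simply propagates
the state. The transition into slot $t$ uses the covariates of slot
$t-1$ — the switching decision precedes the move — which matches how the
synthetic generator runs the process forward.

## Conventions worth knowing

* A step $l_t$ is the displacement *into* slot $t$; the first slot of a
  track has no step, and the first angle needs three consecutive observed
  positions, so it first appears at slot 3. Steps are never bridged across
  missing slots: a two-slot displacement has a different time base and
  would contaminate the 15-minute emission scale the model assumes.
* Zero-length steps are kept at exactly 0 (not jittered). The gamma density
  is not defined there for shapes below 1, so `fit_hmm()` automatically
  adds the zero point mass whenever the data contain exact zeros, and says
  so. The zero atom's pseudo-residual uses the CDF midpoint of the jump.
* States are relabeled after fitting in increasing order of fitted step
  mean, so "state 1" is always the shortest-step state and fits are
  comparable across runs; the likelihood itself is invariant under
  relabeling.

## Fitting: working scale, starts, convergence

`fit_hmm()` maximizes the exact likelihood numerically (BFGS) on an
unconstrained working scale: $\log \mu_k$, $\log \sigma_k$,
$\mathrm{logit}\, \pi_{0,k}$, $\log \kappa_k$ (floored at $10^{-8}$), raw
$\beta$, and the angle mean as a $(\sin, \cos)$ pair, which avoids the wrap
discontinuity at $\pm\pi$ at the cost of one flat direction the optimizer
simply ignores. Start 1 is moment-based — an $N$-quantile split of the
observed steps gives group means and SDs, diagonal transition probabilities
start at 0.8 — and starts 2..`n_starts` perturb it with block-specific
Gaussian noise on the working scale. The best converged start wins; ties
within $10^{-6}$ log-likelihood units go to the earliest start, so results
are deterministic given the seed. Convergence uses `optim`'s relative
tolerance ($10^{-9}$, at most 500 iterations per start). Standard errors,
when requested, come from the numerical Hessian of the working-scale
negative log-likelihood and the delta method.

Multiple starts matter in practice: with three overlapping gammas the
likelihood has local optima where two states share a mean. Twenty-five
starts (the default) has been generous in our experiments — at study scale
every converged start typically reaches the same optimum.

The parameter count entering AIC ($-2\log L + 2p$) is
$p = N(2 + [\text{zero mass}]) + 2N + (1 + p_{\mathrm{cov}})N(N-1) +
(N-1)[\delta\ \text{free}]$.

## Habitat covariates

`derive_covariate_layers()` builds NDVI $= (NIR - R)/(NIR + R)$ from the
reflectance bands, classifies it into vegetation-density classes by 1-D
K-means (classes relabeled so that a higher index always means denser
vegetation; `stats::kmeans` with 10 restarts under a fixed seed), and
computes the exact Euclidean distance transform to the woodland mask.
Distance is 0 anywhere inside woodland: the covariate's role is to penalize
being far from cover, and the transition model needs it defined everywhere.
Covariates attach to tracks by containing-cell lookup with no interpolation
— class rasters are categorical, and mixing interpolated and
nearest-neighbor layers would misalign them. Cells map to positions by
$\lfloor (pos - origin)/res \rfloor$ with centers at
$origin + (i - 0.5) \cdot res$.

Vegetation-density classes observed on fewer than 50 slots are merged into
the nearest class by label before dummy coding (`merge_rare`); with 10
classes and a month of tracking, rare classes otherwise produce separation
and unidentifiable $\beta$ columns.

## What the synthetic generator emulates — and what it does not

`simulate_landscape()` + `simulate_tracks()` generate the full study
design with known truth: a fragmented landscape of circular woodland
patches in pasture (30 m cells), 26 animals (14 males, 12 females), nightly
57-slot tracks, states switching under the true $\Gamma(x)$, dead-reckoned
movement, per-coordinate Gaussian location error, and independent fix
dropout. The generator's defaults are the study conditions: step means
28/103/268 m per 15 minutes, $\pm 20$ m location error, and a missingness
rate (10%) and track length (18 nights $\approx$ 1,026 slots) chosen so
that animals accumulate roughly 1,000 observations each, matching the
field data's per-animal counts. The published analysis reports only the
step means; the remaining generating values — step SDs 25/70/160 m, angle
means $\pi$/0/0, concentrations 0.4/0.6/2.5 — were fixed once at values
typical for a small terrestrial mammal (tortuous denning movement, weakly
directed foraging, strongly directed travel) and are not tuned.

Deliberate simplifications: each night restarts at the animal's den (these
animals den by day and anchor their nightly excursions there; this also
keeps month-long simulations from random-walking into the arena boundary),
with the starting state drawn fresh from the stationary distribution at
the den — tracks are independent in the likelihood, so the generator
matches that assumption rather than carrying state across the day gap.
Steps that would leave the landscape are redrawn (up to 100 times, then
reflected; reflections are counted and essentially never occur). Redrawing
truncates the longest excursions slightly, which on a 12 km arena biases
the fast-traveling state's realized mean step by about a percent — the
recovery experiments use that arena size so the effect stays well inside
estimation error. The
generator does not emulate duplicate or off-schedule fixes, collar failure
runs, territorial interactions, or realistic Landsat radiometry — NDVI
contrast between woodland and pasture is what matters downstream, not
radiometric calibration. Passing recovery tests on these data therefore
demonstrates correctness of the estimator under the model's assumptions,
not robustness to every artifact of real telemetry.

In recovery experiments whose generating parameters are the *fitted*
observation-scale estimates (e.g. the 28 m short-step mean, which already
contains the stationary collar error), the generator is run with
`gps_error_sd = 0`: layering another 20 m of noise on top would
double-count location error.

## Diagnostics and downstream inference

* **Viterbi decoding** gives the jointly most probable state path (ties
  toward the lower state index); posterior state proportions by site or
  sex come from `activity_budget()`.
* **Pseudo-residuals** are ordinary one-step-ahead probability integral
  transforms, $u_t = P(X_t \le x_t \mid x_{1:t-1})$, mixing each channel's
  CDF over the forward predictive state weights; under a correctly
  specified model they are standard uniform. Values of exactly 0/1 are
  clamped at $10^{-12}$.
* **State-count choice**: AIC systematically favors more states, so
  `select_states()` reports AIC (with the within-2 parsimony rule) and
  per-channel Kolmogorov-Smirnov statistics of the pseudo-residuals side
  by side instead of auto-deciding.
* **Stationary profiles** (`stationary_profile()`) sweep one covariate
  over its training range while holding other numeric covariates at their
  training means and categoricals at their reference level (both
  overridable), solving $\delta(I - \Gamma + U) = 1$ at each grid point.

## Problem sizes used in the validation suite

The package's tests validate the machinery at sizes chosen to exercise the
study design while staying desk-sized: oracle equivalence of the forward
and Viterbi recursions against exhaustive path enumeration on 100 random
instances ($N \le 3$, $T \le 8$); parameter recovery at full study scale
(26 animals $\times$ 18 nights, 25 starts); state-count selection on 20
replicates of 10 animals $\times$ 8 nights — the smallest size at which
the fitted 2-state model's residual miscalibration reliably exceeds
Kolmogorov-Smirnov sampling noise (at full scale the 3-vs-2-state AIC gap
is in the thousands); pseudo-residual calibration on 100 replicates of 3
animals $\times$ 2 nights, with the comparative wrong-model check at 8
$\times$ 5; and stationary-profile recovery from a 26-animal, 12-night
covariate-driven simulation on a woodland-mosaic landscape chosen so both
ends of the canopy gradient are visited. The empirical state-frequency
check runs a $>10^5$-slot covariate-free chain.

## Known limitations

* Location error enters only through the generator and the interpretation
  of the short-step state; there is no state-space filtering of positions.
* No random effects across individuals, no hierarchical or semi-Markov
  structure, and no formal hypothesis tests on $\beta$ — model comparison
  is by AIC ranking, as in the analysis this package reimplements.
* `select_states()` reports its two criteria; when they disagree the call
  is the analyst's.
* The K-means vegetation classification is 1-D (NDVI only); texture or
  multi-band classifications are out of scope.
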