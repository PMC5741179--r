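---
title: "Joint modelling of a longitudinal outcome and semicompeting risks of dropout and death"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of a longitudinal outcome and semicompeting risks of dropout and death}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In long-term cohort studies a scheduled longitudinal outcome — the
motivating example is square-root CD4 cell count measured at up to twelve
visits — is truncated by two very different events. Patients *drop out*,
after which their outcome still exists but is unobserved, and patients
*die*, after which the outcome is not defined at all. Death can end the
dropout process but dropout does not end the observation of death (deaths
are typically ascertained from registries after withdrawal), so the two
events are *semicompeting* rather than competing risks. Both processes may
be informative: patients with steeper CD4 decline are more likely to leave
the study and more likely to die.

Three inferential targets must then be distinguished. The *unconditional*
(immortal-cohort) mean profile `E(Y_ij | x_ij)` implicitly extrapolates the
outcome beyond death. The *fully conditional* approach stratifies on the
realized death time, which censored death times do not allow. This package
implements a likelihood-based route to the *partly conditional*
(mortal-cohort) profile `E(Y_ij | S_i >= j, x_ij)` — the mean among
patients still alive at visit `j` — while accommodating informative
dropout, censoring of the death time, and intermittent (ignorably) missing
measurements.

## The model

For patient `i` at visit `j = 1, ..., M`:

* Longitudinal submodel: `Y_ij = x_ij' beta + z_ij' b_i + eps_ij` with
  `eps_ij ~ N(0, sigma2_eps)` independent and `b_i ~ N(0, Sigma)`. The
  default random design is an intercept and slope, `z_ij = (1, j)`.
* Discrete-time probit hazard of dropout:
  `P(D_i = j | D_i >= j, b_i) = 1 - Phi(x_D,ij' alpha_D + (W_D b_i)' gamma_D)`.
* Discrete-time probit hazard of death:
  `P(S_i = j | S_i >= j, b_i) = 1 - Phi(x_S,ij' alpha_S + (W_S b_i)' gamma_S)`.

The association parameters `gamma_D`, `gamma_S` load the shared random
effects into the hazards; when both are zero, dropout and death are
ignorable given the observed data. Given `b_i`, the complete outcome
vector, the dropout time and the death time are assumed independent.

With independent censoring at `C_i`, the observed record is
`D*_i = min(D_i, S_i, C_i)`, `delta_D = 1[D_i <= C_i, D_i <= S_i]`,
`S*_i = min(S_i, C_i)`, `delta_S = 1[S_i <= C_i]`, plus the longitudinal
rows at attended visits up to `D*_i`. All four indicator patterns occur:
completers (0,0), dropout only (1,0), death without prior dropout (0,1),
and dropout followed by an observed death (1,1).

`Sigma` is parameterized by its modified Cholesky decomposition
`L Sigma L' = G`: generalized autoregressive parameters `lambda_kl`
(unconstrained) and innovation variances `sigma2_k > 0`. Positivity of the
innovation variances is the only constraint needed for positive
definiteness, which makes unconstrained optimization and prior
specification straightforward. For the intercept/slope case,
`Sigma = [[s1, l*s1], [l*s1, l^2*s1 + s2]]`.

## The closed-form marginal likelihood

Given `b`, each event process contributes a product of probit terms: one
survival factor `Phi(lp_j)` per visit before the observed time and a
terminal factor that is the hazard (sign flip via `1 - Phi(x) = Phi(-x)`)
if the event was observed. Collecting both processes gives
`prod_k Phi(s_k (a_k + c_k' b))` with `K = D* + S*` terms (up to `2M`).

Writing each `Phi` as `P(eps_k <= .)` for iid standard normal `eps_k` and
marginalizing `b ~ N(mu, Sigma_b)` yields the identity implemented by
`expectation_probit_product()`:

```
E[ prod_k Phi(s_k (a_k + c_k' b)) ] = Phi_K(u; I_K + A Sigma_b A'),
u_k = s_k (a_k + c_k' mu),  row k of A = s_k c_k'.
```

The patient's marginal likelihood is the Gaussian marginal of the observed
rows (mean `X beta`, covariance `Z Sigma Z' + sigma2_eps I`) times this
`K`-dimensional normal probability evaluated at the posterior moments of
`b` given those rows. The derivation is locked in by tests: a tensor
Gauss–Hermite oracle at relative error `1e-4` on fifty random patients, a
`10^7`-draw Monte-Carlo oracle for the hardest `K = 24` completer case,
exact factorization at `gamma = 0`, and a total-probability enumeration
over the whole semicompeting outcome space.

## Survivor-conditional moments and mortal-cohort profiles

Conditioning `b` on `S >= j` (surviving the death hazards of visits
`1..j-1`) produces a closed skew-normal law. Its normalizing constant is
the marginal survival probability `Phi_{j-1}(u; I + A Sigma A')` with
`u_k = x_S,ik' alpha_S`, and its mean is

```
E(b | S >= j) = Sigma A' grad_u log Phi_{j-1}(u; I + A Sigma A'),
```

where each partial `d Phi_K / d u_k` is a univariate normal density times a
conditional `(K-1)`-dimensional CDF. The partly conditional profile is then
`x_ij' beta + z_ij' E(b | S >= j)`; with posterior draws it is computed per
draw, giving bands. Both the scalar analytic identity (via Stein's lemma)
and a rejection-sampling oracle pin the formula down in the tests. With a
positive slope association (`gamma_S2 > 0`), survivors are selected towards
flatter trajectories, so the mortal-cohort profile lies above the
unconditional joint-model profile with a gap that grows over visits.

Two conventions for "alive at visit `j`" are supported: the default
conditions on surviving hazards `1..j-1` (so `S >= 1` is vacuous), and
`alive_through = TRUE` additionally includes visit `j`'s hazard. The needed
CDF dimension is at most `M - 1` (or `M`), roughly half that of the
likelihood.

## Estimation

**Maximum likelihood** (`fit_mle()`) maximizes the marginal likelihood over
the unconstrained parameterization (raw coefficients, `lambda`, log
variances) with Nelder–Mead plus one restart, iteration cap 2000 by
default. Two evaluation routes for the probit-product expectation are
provided:

* `"orthant"` — the Genz quasi-Monte-Carlo normal probability
  (`mvtnorm::pmvnorm`, absolute tolerance `1e-6`). The algorithm consumes
  R's RNG stream, so it runs under a saved/restored `.Random.seed` with a
  fixed internal seed: the likelihood is then a deterministic function of
  the parameters. Dimensions 2–3 use the deterministic TVPACK routine.
* `"gh"` — tensor Gauss–Hermite quadrature over the `q`-dimensional
  random-effects space on the posterior-standardized scale (default 20
  nodes per dimension, Golub–Welsch construction). For `q <= 2` this is
  both much faster and smooth in the parameters, avoiding the optimization
  plateau created by any fixed-tolerance probability evaluation; it is the
  default inside the optimizer. The two routes agree to within the orthant
  tolerance in the tests.

Hessian-based standard errors are computed on request and flagged when the
curvature is within an order of magnitude of the probability-evaluation
tolerance. Because that regime is easy to hit in practice,
`profile_ci()` provides the preferred intervals: a 10-point profile of the
log-likelihood around the MLE, smoothed by quadratic least squares (the
smoothing absorbs residual evaluation noise), with the likelihood-ratio
drop `qchisq(0.95, 1) / 2`. For an exactly quadratic profile this
reproduces the Wald interval; a non-concave profile triggers one grid
widening with a warning.

`fit_lmm_ignorable()` is the comparator that treats dropout and death as
ignorable: the same longitudinal submodel fitted by ML to the observed rows
only, with the fixed effects profiled out by GLS at each variance-parameter
value. Under informative truncation its time slope is attenuated relative
to the joint model.

**Bayesian estimation** (`sample_posterior()`) keeps the `b_i` as latent
variables, so no normal probabilities are needed. The sampler combines
three ingredients:

* *Truncated-normal augmentation* of each probit Bernoulli (one per
  at-risk visit and process) in the Albert–Chib fashion, which makes the
  `b_i` updates conjugate Gaussian (vectorized across patients for
  `q = 2`), alongside conjugate updates for `beta`, the `lambda`
  regressions of the modified Cholesky decomposition, and inverse-gamma
  updates for `sigma2_eps` and the innovation variances. Tail-stable
  inverse-CDF sampling is used for the truncated normals.
* *Collapsed Metropolis–Hastings updates of the hazard blocks*
  `(alpha_D, gamma_D)` and `(alpha_S, gamma_S)`: each block is updated
  from its conditional given `b` with the truncated-normal latents
  integrated out, using a Newton proposal built from the observed
  information of the probit log-likelihood, after which the latents are
  redrawn (a partially collapsed Gibbs step). Plain augmentation mixes
  extremely slowly for the death-model associations — death is a rare
  event and the augmented sufficient statistics move in tiny steps — and
  this is why BUGS-style fits of such models need tens of thousands of
  draws; the collapsed update removes most of that random walk. Each
  block update composes the MH step with a conjugate draw given the
  refreshed latents, pairing large in-basin jumps with diffusive moves.
* A *compiled implementation* (RcppArmadillo) of the whole iteration; a
  pure-R reference implementation of the identical algorithm is retained
  (`impl = "r"`) and the two are compared distributionally in the tests.

Default priors: `N(0, 100)` on `beta` and `lambda`, weakly informative
`N(0, 4)` on the probit-scale `alpha` and `gamma`, `IG(0.001, 0.001)` on
`sigma2_eps`, `IG(0.01, 1)` on the innovation variances — all overridable
through `jm_prior()`.

Three chains are the default, started from two-stage estimates (least
squares for the longitudinal part, ridge-estimated random effects, probit
regressions on them for the hazards) with chain-specific dispersion
scaled to a plausible posterior spread; Gelman–Rubin statistics and
effective sizes come from `diagnostics()`. Correctness of the target is
validated three independent ways in the test suite: against a JAGS run of
the same model (`engine = "jags"`), against the closed-form posterior in
a conjugate subcase, and by simulation-based calibration (rank
uniformity) on a reduced model. For final inference a pooled posterior of
tens of thousands of draws is appropriate; the tests use far fewer and
pool the chains.

## The simulator

`hers_like_config()` fixes the study conditions the package is tested
under: `M = 12` visits (a 3-month first interval, then 6-month intervals,
2093 days total), `N = 827` patients, a square-root-CD4-like outcome with
random intercept and slope, hazard designs with quadratic time (`j/M`,
`(j/M)^2`), a four-level baseline viral-load factor, a 0–5 symptom count
and a therapy indicator, true parameter values equal to the fitted HERS
posterior means, administrative censoring at the final visit, and 7.6%
intermittent missingness (never at the enrolment visit). Baseline
covariate frequencies (viral-load group probabilities 0.25/0.30/0.25/0.20,
symptom count Binomial(5, 0.2), therapy rate 0.35) are plausible values
chosen once for a cohort of this kind; the simulator does not attempt to
match the real covariate joint distribution, nor does it simulate
continuous event times (a user can discretize their own via
`discretize_time()`).

Design conventions, where the observation scheme is genuinely ambiguous:

* A patient whose record ends by dropout attended visit `D*` (the dropout
  time is "the last attended visit"), so that visit is observed.
* No measurement is taken in the interval where death terminates follow-up
  (`obs_at_death_interval = FALSE` by default; both conventions supported).
* Intermittent missingness is MCAR by default, matching the ignorability
  assumption; an MAR-on-previous-outcome option exists for robustness
  experiments only.
* Death after censored dropout uses only `C` (never `D`) in `S*`,
  preserving the semicompeting structure.
* Per-patient L'Ecuyer-CMRG substreams make patient `i`'s data invariant
  to the total sample size.

Passing parameter-recovery tests on these synthetic cohorts shows the
estimators are correct under the model's own assumptions; it cannot show
robustness to misspecification of the trajectory shape, the probit link,
or the conditional-independence assumption, none of which the simulator
violates.

## Posterior predictive assessment

`ppc_probability()` implements a chi-square discrepancy check: per
posterior draw, replicated observed data are produced by drawing fresh
random effects, complete outcomes, dropout and death times, truncating at
`min(D_rep, S_rep, M)`; the discrepancy
`sum_i (Y_i - X_i beta)' Omega_i^{-1} (Y_i - X_i beta) / n_total` (random
effects integrated out) is compared between the real and replicated data at
the same draw. Replicated intermittent missingness is not simulated — only
the truncation process is replicated — and ties count one half. Values
near 0 or 1 indicate misfit; the tests verify calibration under a correct
fit and detection of a ten-fold residual-variance misspecification.

## Numerical choices and limitations

* Probit linear predictors are capped at ±37.5 before any non-log-domain
  use; log-domain accumulation (`pnorm(log.p = TRUE)`) is used throughout.
* Orthant probabilities are floored at the smallest positive double before
  taking logs; a survival probability underflowing to zero in the
  conditional-mean computation raises an error rather than returning noise.
* The interval convention is half-open `[left, right)` with the last
  interval closed, so interior cutpoints belong to the later interval and
  the map onto visits is a total surjection.
* Visit-varying association parameters (`gamma_by_visit = TRUE`) are
  supported structurally in the likelihood, the simulator and the
  closed-form profiles, but the samplers and optimizer defaults assume the
  visit-constant case actually used in the motivating analysis.
* Residual covariance is `sigma2_eps I` only; serial-correlation
  structures, non-Gaussian outcomes, continuous-time hazards and frailty
  terms beyond `b_i` are out of scope.
* Problem sizes in the test suite (e.g. cohorts of 40–500 patients, 3–12
  visits, hundreds to a few thousand retained draws, 100-replicate
  coverage studies) are the package's chosen desk-scale study conditions;
  the same code runs unchanged at larger sizes.
* At those desk-scale conditions the death process is the weakest-
  identified part of the model: a 6-visit, 500-patient cohort at the
  default parameter values yields only ~11% deaths. The package's
  replicate studies recover the longitudinal fixed effects with small
  bias and nominal interval coverage, and the hazard associations within
  the same bands but with the largest relative biases (up to about half a
  posterior SD for the dropout-slope association). Weak identification
  also creates a minor posterior region in which deaths are attributed to
  baseline covariates rather than the shared random effects; the
  sampler's hazard blocks therefore combine a collapsed
  Metropolis–Hastings update with a conjugate augmentation update, so
  chains neither random-walk through the main region nor stick in the
  minor one. Mortal-cohort profile estimates inherit their extra
  uncertainty from exactly these parameters.

## A worked example

```{r}
library(semijm)
cfg <- hers_like_config(N = 500, M = 6)
d <- simulate_dataset(cfg, seed = 1)
draws <- sample_posterior(d, chains = 3, warmup = 500, draws = 1500,
                          seed = 1)
summary(draws)
diagnostics(draws)
pattern <- data.frame(vl_low = 1, vl_med = 0, vl_high = 0,
                      symptoms = 1, therapy = 1)
partly_conditional_profile(draws, cfg$design, pattern, M = 6)
ppc_probability(draws, d, thin = 3, seed = 2)
```
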