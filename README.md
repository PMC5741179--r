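# semijm

Joint models for a Gaussian longitudinal outcome truncated by
**semicompeting risks of dropout and death**, with closed-form
mortal-cohort ("alive at visit j") inference.

## The problem

In long-term cohort studies — the motivating setting is repeated CD4 cell
counts in an HIV cohort with twelve scheduled visits — observation of the
longitudinal outcome ends either when a patient withdraws (dropout) or
when the patient dies. The two are *semicompeting*: death terminates the
dropout process, but deaths remain observable from registries after
dropout. Both can be informative, because the same disease progression
that drives the outcome also drives withdrawal and mortality. Fitting an
ordinary linear mixed model to the observed rows then underestimates the
rate of decline, while a joint model that corrects the selection bias
implicitly extrapolates the outcome beyond death. Clinically one often
wants neither of these, but the profile of the **mortal cohort**: the mean
outcome among patients still alive at each visit.

`semijm` is for biostatisticians analysing such data. It implements:

* a linear mixed model `Y_ij = x_ij'β + z_ij'b_i + ε_ij` (random
  intercept and slope by default) linked to **discrete-time probit
  hazards** of dropout and death,
  `P(event at j | at risk) = 1 − Φ(x'α + (W b_i)'γ)`, through the shared
  random effects `b_i ~ N(0, Σ)`, with `Σ` in its modified Cholesky
  parameterization (`LΣL' = G`);
* the **closed-form marginal likelihood**: integrating `b_i` out of the
  product of up to `2M` probit terms gives a single multivariate normal
  probability with covariance `I + AΣ_bA'`;
* maximum likelihood (Nelder–Mead, profile-likelihood 95% intervals) and
  Bayesian estimation: a compiled Gibbs sampler with truncated-normal
  augmentation and collapsed Metropolis–Hastings updates of the hazard
  blocks (a JAGS engine serves as an independent cross-check);
* **partly conditional profiles** `E(Y_ij | S_i ≥ j, x) = x'β +
  z'E(b | S ≥ j)` from the closed skew-normal law of the random effects
  given survival — `E(b | S ≥ j) = ΣA'∇log Φ_{j−1}(u; I + AΣA')`;
* posterior predictive model checking with a χ² discrepancy;
* a simulator for HERS-like cohorts (12 visits, informative dropout and
  death, independent censoring, 7.6% intermittent missingness) with known
  truth, and a `semijm` command-line interface
  (`simulate`, `loglik`, `fit-ml`, `fit-bayes`, `profiles`, `ppc`).

## Worked example

Simulate a 300-patient, 6-visit cohort at the fitted HERS parameter
values, sample the posterior, and compare immortal- and mortal-cohort
profiles:

```r
library(semijm)
cfg <- hers_like_config(N = 300, M = 6)
d <- simulate_dataset(cfg, seed = 1)
print(d)
#> Joint-model dataset: N = 300 patients, 1360 longitudinal observations, M = 6
#>        delta_S
#> delta_D   0   1
#>       0 155  24
#>       1 101  20
```

All four dropout/death patterns occur: completers, dropout only, death
only, dropout followed by observed death.

```r
draws <- sample_posterior(d, chains = 2, warmup = 500, draws = 1500, seed = 1)
summary(draws)
#>   parameter    mean     sd    q2.5  q97.5
#>      beta.1 14.3038 0.8516 12.5817 15.924
#>  beta.visit -0.8169 0.2048 -1.2167 -0.421
#>    alphaD.1  1.0579 0.2219  0.6381  1.515
#>    gammaD.1  0.0183 0.0134 -0.0101  0.042
#>    gammaD.2  0.3171 0.1428  0.0712  0.622
#>    gammaS.1  0.1101 0.1164 -0.3087  0.230
#>    gammaS.2  1.5305 0.5964  0.3456  2.884
#>  sigma2_eps  7.8217 0.4688  7.0615  8.957
```

The posterior recovers the generating values (time slope −0.863, dropout
association γ₂ᴰ = 0.443, death association γ₂ˢ = 1.192, σ²\_ε = 7.304): a
positive γ₂ˢ means patients with flatter trajectories survive longer.

```r
pattern <- data.frame(vl_low = 1, vl_med = 0, vl_high = 0,
                      symptoms = 1, therapy = 1)
partly_conditional_profile(draws, cfg$design, pattern, M = 6, draw_thin = 10)
#>  visit unconditional conditional p_alive
#>      1          18.6        18.6   1.000
#>      2          18.4        18.5   0.995
#>      3          18.3        18.3   0.987
#>      4          18.1        18.2   0.978
#>      5          17.9        18.1   0.967
#>      6          17.8        18.1   0.956
```

The mortal-cohort (conditional) profile starts at the unconditional value
and lies increasingly above it as survivor selection accumulates — the
square-root CD4 decline among those still alive is flatter than the
immortal-cohort extrapolation.

```r
ppc_probability(draws, d, thin = 6, seed = 2)
#> Posterior predictive check (chi-square discrepancy)
#>   p = 0.55 over 500 replicates
#>   observed statistic: 0.9848  replicated: 0.9936
```

A predictive probability near 0.5 indicates the fitted model reproduces
the observed data's second-moment structure; values near 0 or 1 flag
misfit.

The same pipeline is available from a shell via `inst/exec/semijm`
(`simulate → fit-bayes → profiles → ppc`), with all randomness controlled
by `--seed`.

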