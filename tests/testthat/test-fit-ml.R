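test_that("with no association the MLE matches the closed-form LMM", {
  # balanced complete data, random intercept only: the one-way
  # random-effects ML estimates are available in closed form
  des <- jm_design(fixed = "1", random = "1", dropout = "1", death = "1")
  M <- 5; N <- 40
  prm <- jm_params(beta = 10, alpha_D = 40, gamma_D = 0, alpha_S = 40,
                   gamma_S = 0, sigma2_eps = 4,
                   cov = cholesky_cov(numeric(0), 9))
  cfg <- sim_config(N = N, scheme = tiny_scheme(M), design = des,
                    params = prm, covariate_generator = null_covars,
                    p_int = 0)
  d <- simulate_dataset(cfg, seed = 53)
  ym <- matrix(d$long$y[order(d$long$id, d$long$visit)], N, M, byrow = TRUE)
  ybar_i <- rowMeans(ym)
  W <- sum((ym - ybar_i)^2)
  Bv <- sum((ybar_i - mean(ym))^2)
  beta_hat <- mean(ym)
  s2e_hat <- W / (N * (M - 1))
  s2b_hat <- (M * Bv / N - s2e_hat) / M
  fit <- fit_mle(d, init = prm,
                 fixed = c(gammaD.1 = 0, gammaS.1 = 0),
                 control = list(maxit = 2000, reltol = 1e-12))
  expect_equal(fit$params$beta, beta_hat, tolerance = 1e-4)
  expect_equal(fit$params$sigma2_eps, s2e_hat, tolerance = 1e-4)
  expect_equal(fit$params$cov$innovation_vars, s2b_hat, tolerance = 1e-4)
  # accepted-step log-likelihood trace never decreases
  expect_true(all(diff(fit$monitor) >= 0))
})

test_that("the ignorable LMM fit agrees with an independent mixed-model fit", {
  skip_if_not_installed("nlme")
  d <- simulate_dataset(tiny_config(N = 80, M = 5, p_int = 0.1), seed = 55)
  fit <- fit_lmm_ignorable(d)
  lme_fit <- nlme::lme(y ~ visit, random = ~ visit | id,
                       data = d$long, method = "ML",
                       control = nlme::lmeControl(opt = "optim"))
  expect_equal(unname(fit$beta), unname(nlme::fixef(lme_fit)),
               tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lme_fit)),
               tolerance = 1e-6)
  vc <- matrix(as.numeric(nlme::getVarCov(lme_fit)), 2)
  expect_equal(unname(fit$Sigma), vc, tolerance = 0.02)
})

test_that("joint MLE recovers generating parameters on simulated data", {
  des <- jm_design(fixed = c("1", "visit"), random = c("1", "visit"),
                   dropout = "1", death = "1")
  prm <- jm_params(beta = c(12, -0.7), alpha_D = 1.3, gamma_D = c(0.03, 0.4),
                   alpha_S = 2.2, gamma_S = c(0.1, 0.9), sigma2_eps = 6,
                   cov = cov_from_moments(20, 0.5, -0.3))
  cfg <- sim_config(N = 80, scheme = tiny_scheme(6), design = des,
                    params = prm, covariate_generator = null_covars,
                    p_int = 0)
  d <- simulate_dataset(cfg, seed = 57)
  fit <- fit_mle(d, init = prm,
                 control = list(maxit = 1500, restarts = 1, gh_nodes = 8,
                                hessian = TRUE))
  ll_truth <- marginal_loglik_dataset(d, prm, method = "gh", gh_nodes = 12)
  expect_gte(fit$loglik, ll_truth)        # optimality sanity
  tv <- semijm:::params_to_vector
  z <- abs(tv(fit$params) - tv(prm)) / fit$se
  expect_gte(mean(z < 3, na.rm = TRUE), 0.9)
})

test_that("quadratic profiles reproduce the Wald interval exactly", {
  # an exactly quadratic log-likelihood: smoothing is lossless and the
  # likelihood-ratio interval equals estimate +/- 1.96 se
  se <- 0.37; mle <- 1.42
  tvals <- seq(mle - 2 * se, mle + 2 * se, length.out = 10)
  lvals <- -0.5 * ((tvals - mle) / se)^2
  sm <- semijm:::quad_profile_interval(tvals, lvals)
  expect_equal(sm$estimate, mle, tolerance = 1e-6)
  expect_equal(sm$lower, mle - qnorm(0.975) * se, tolerance = 1e-6)
  expect_equal(sm$upper, mle + qnorm(0.975) * se, tolerance = 1e-6)
  # on a symmetric grid the smoothed estimate stays within half a step
  # of the unsmoothed argmax even for a mildly cubic profile
  lv2 <- lvals + 0.02 * ((tvals - mle) / se)^3
  sm2 <- semijm:::quad_profile_interval(tvals, lv2)
  step <- diff(tvals)[1]
  expect_lt(abs(sm2$estimate - tvals[which.max(lv2)]), step / 2 + 1e-12)
})

test_that("profile-likelihood intervals for the time slope cover the truth", {
  des <- jm_design(fixed = c("1", "visit"), random = "1",
                   dropout = "1", death = "1")
  prm <- jm_params(beta = c(10, -0.5), alpha_D = 1.2, gamma_D = 0,
                   alpha_S = 1.8, gamma_S = 0, sigma2_eps = 4,
                   cov = cholesky_cov(numeric(0), 9))
  cfg <- sim_config(N = 40, scheme = tiny_scheme(4), design = des,
                    params = prm, covariate_generator = null_covars,
                    p_int = 0)
  hits <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    d <- simulate_dataset(cfg, seed = 6000 + r)
    fit <- fit_mle(d, init = prm, fixed = c(gammaD.1 = 0, gammaS.1 = 0),
                   control = list(maxit = 800, restarts = 0,
                                  hessian = TRUE))
    ci <- profile_ci(d, fit, "beta.visit", maxit = 250)
    hits <- hits + as.integer(ci$lower <= -0.5 && -0.5 <= ci$upper)
  }
  expect_gte(hits / n_rep, 0.89)
  expect_lte(hits / n_rep, 0.99)
})
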