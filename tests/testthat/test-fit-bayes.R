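empty_data <- function() {
  des <- tiny_design(pD = "1", pS = "1")
  jm_data(data.frame(id = integer(0), visit = integer(0), y = numeric(0)),
          data.frame(id = integer(0), D_star = integer(0),
                     delta_D = integer(0), S_star = integer(0),
                     delta_S = integer(0), z0 = numeric(0)),
          tiny_scheme(4), des)
}

test_that("with no data the sampler reproduces the prior", {
  pr <- jm_prior(innov_ig = c(3, 3))
  dr <- sample_posterior(empty_data(), prior = pr, chains = 1,
                         warmup = 200, draws = 4000, seed = 7)
  dm <- dr$draws
  n <- nrow(dm)
  # normal blocks: mean 0, prior variance
  for (par in c("beta.1", "beta.visit", "lambda.1")) {
    expect_lt(abs(mean(dm[, par])), 3 * 10 / sqrt(n))
    expect_lt(abs(var(dm[, par]) - 100), 3 * sqrt(2) * 100 / sqrt(n))
  }
  for (par in c("alphaD.1", "gammaD.1", "gammaS.2")) {
    expect_lt(abs(mean(dm[, par])), 3 * 2 / sqrt(n))
    expect_lt(abs(var(dm[, par]) - 4), 3 * sqrt(2) * 4 / sqrt(n))
  }
  # innovation variances: 1/sigma2 ~ Gamma(3, 3), mean 1, var 1/3
  for (par in c("innov.1", "innov.2")) {
    prec <- 1 / dm[, par]
    expect_lt(abs(mean(prec) - 1), 3 * sqrt(1 / 3 / n))
  }
})

test_that("the conjugate subcase matches the closed-form GLS posterior", {
  # gamma = 0 and all variance parameters known: the beta posterior is
  # multivariate normal with precision sum X' V^-1 X + I / 100
  prm <- tiny_params(gamma_D = c(0, 0), gamma_S = c(0, 0))
  d <- simulate_dataset(tiny_config(N = 60, M = 4, params = prm,
                                    p_int = 0.1), seed = 59)
  dr <- sample_posterior(
    d, chains = 1, warmup = 300, draws = 4000, seed = 9,
    fixed = list(gamma_D = c(0, 0), gamma_S = c(0, 0),
                 sigma2_eps = prm$sigma2_eps, lambda = prm$cov$lambda,
                 innov = prm$cov$innovation_vars))
  prec <- diag(1 / 100, 2)
  rhs <- rep(0, 2)
  for (i in 1:60) {
    pt <- patient_i(d, i)
    if (pt$n == 0) next
    Z <- matrix(pt$Z, nrow = pt$n)
    V <- Z %*% tcrossprod(prm$Sigma, Z) + prm$sigma2_eps * diag(pt$n)
    Vi <- solve(V)
    prec <- prec + crossprod(pt$X, Vi %*% pt$X)
    rhs <- rhs + crossprod(pt$X, Vi %*% pt$y)
  }
  post_mean <- drop(solve(prec, rhs))
  post_sd <- sqrt(diag(solve(prec)))
  neff <- diagnostics(list(dr$draws[, 1:2]))$n_eff
  for (k in 1:2)
    expect_lt(abs(mean(dr$draws[, k]) - post_mean[k]),
              3 * post_sd[k] / sqrt(neff[k]) + 0.02 * post_sd[k])
})

test_that("posterior draws respect the variance constraints", {
  d <- simulate_dataset(tiny_config(N = 40, M = 4), seed = 61)
  dr <- sample_posterior(d, chains = 1, warmup = 100, draws = 300, seed = 11)
  expect_true(all(dr$draws[, "sigma2_eps"] > 0))
  expect_true(all(dr$draws[, c("innov.1", "innov.2")] > 0))
  sig <- semijm:::derived_sigma_draws(dr)
  expect_true(all(sig[, "var_b1"] * sig[, "var_b2"] -
                    sig[, "cov_b12"]^2 > 0))
})

test_that("posterior concentrates on the truth in a scaled-down cohort", {
  cfg <- hers_like_config(N = 400, M = 6)
  d <- simulate_dataset(cfg, seed = 63)
  dr <- sample_posterior(d, chains = 3, warmup = 600, draws = 2400,
                         thin = 2, seed = 13)
  s <- summary(dr)
  tv <- cfg$params
  truth <- c(tv$beta, tv$alpha_D, tv$gamma_D, tv$alpha_S, tv$gamma_S,
             tv$sigma2_eps, tv$cov$lambda, tv$cov$innovation_vars)
  k <- seq_along(truth)
  expect_true(all(abs(s$mean[k] - truth) < 3.5 * s$sd[k]))
  dg <- diagnostics(dr)
  expect_lt(max(dg$rhat[seq_along(truth)]), 1.05)
})

test_that("gibbs and JAGS engines target the same posterior", {
  skip_if_not_installed("rjags")
  d <- simulate_dataset(tiny_config(N = 120, M = 4, p_int = 0.1), seed = 65)
  g <- sample_posterior(d, chains = 1, warmup = 600, draws = 2500, seed = 15)
  j <- sample_posterior(d, chains = 1, warmup = 600, draws = 2500, seed = 15,
                        engine = "jags")
  sg <- summary(g); sj <- summary(j)
  eg <- diagnostics(list(g$draws))$n_eff
  ej <- diagnostics(list(j$draws))$n_eff
  k <- seq_len(ncol(g$draws))
  z <- abs(sg$mean[k] - sj$mean[k]) /
    sqrt(sg$sd[k]^2 / pmax(eg, 20) + sj$sd[k]^2 / pmax(ej, 20))
  expect_lt(mean(z > 4), 0.15)
  expect_lt(max(abs(sg$mean[k] - sj$mean[k]) / pmax(sg$sd[k], 1e-6)), 1)
})

test_that("compiled and reference samplers target the same posterior", {
  d <- simulate_dataset(tiny_config(N = 100, M = 4, p_int = 0.1), seed = 75)
  a <- sample_posterior(d, chains = 1, warmup = 300, draws = 1500, seed = 5,
                        impl = "cpp")
  b <- sample_posterior(d, chains = 1, warmup = 300, draws = 1500, seed = 5,
                        impl = "r")
  sa <- summary(a); sb <- summary(b)
  ea <- diagnostics(list(a$draws))$n_eff
  eb <- diagnostics(list(b$draws))$n_eff
  k <- seq_len(ncol(a$draws))
  z <- abs(sa$mean[k] - sb$mean[k]) /
    sqrt(sa$sd[k]^2 / pmax(ea, 10) + sb$sd[k]^2 / pmax(eb, 10))
  expect_lt(max(z), 4)
  expect_lt(max(abs(sa$sd[k] / sb$sd[k] - 1)), 0.5)
})

test_that("agreement between posterior mean and MLE on a larger dataset", {
  # Bernstein-von Mises sanity on the ignorable submodel
  prm <- tiny_params(gamma_D = c(0, 0), gamma_S = c(0, 0))
  d <- simulate_dataset(tiny_config(N = 400, M = 5, params = prm), seed = 67)
  dr <- sample_posterior(d, chains = 1, warmup = 300, draws = 900, seed = 17)
  lmm <- fit_lmm_ignorable(d)
  s <- summary(dr)
  for (k in 1:2)
    expect_lt(abs(s$mean[k] - lmm$beta[k]), 2.5 * s$sd[k])
  expect_lt(abs(s$mean[s$parameter == "sigma2_eps"] - lmm$sigma2_eps),
            2.5 * s$sd[s$parameter == "sigma2_eps"])
})

test_that("rank statistics are uniform under prior resimulation", {
  # simulation-based calibration of a reduced model: scalar random effect,
  # three visits, tight proper priors shared by generator and sampler
  pr <- jm_prior(beta_var = 1, lambda_var = 1, assoc_var = 0.25,
                 sigma2_eps_ig = c(4, 4), innov_ig = c(4, 4))
  des <- jm_design(fixed = "1", random = "1", dropout = "1", death = "1")
  sch <- tiny_scheme(3)
  n_rep <- 200L
  L <- 24L   # posterior draws kept per replicate (thinned)
  ranks <- matrix(NA_integer_, n_rep, 3,
                  dimnames = list(NULL, c("beta", "alphaD", "sigma2_eps")))
  set.seed(19)
  for (r in seq_len(n_rep)) {
    th <- list(beta = rnorm(1, 0, 1), alpha_D = rnorm(1, 0, 0.5),
               gamma_D = rnorm(1, 0, 0.5), alpha_S = rnorm(1, 0, 0.5),
               gamma_S = rnorm(1, 0, 0.5),
               s2e = 1 / rgamma(1, 4, 4), innov = 1 / rgamma(1, 4, 4))
    prm <- jm_params(th$beta, th$alpha_D, th$gamma_D, th$alpha_S,
                     th$gamma_S, th$s2e,
                     cholesky_cov(numeric(0), th$innov))
    cfg <- sim_config(N = 12, scheme = sch, design = des, params = prm,
                      covariate_generator = null_covars, p_int = 0)
    d <- simulate_dataset(cfg, seed = 20000 + r)
    dr <- sample_posterior(d, prior = pr, chains = 1, warmup = 150,
                           draws = L * 8, thin = 8, seed = 30000 + r)
    ranks[r, "beta"] <- sum(dr$draws[, "beta.1"] < th$beta)
    ranks[r, "alphaD"] <- sum(dr$draws[, "alphaD.1"] < th$alpha_D)
    ranks[r, "sigma2_eps"] <- sum(dr$draws[, "sigma2_eps"] < th$s2e)
  }
  # each rank is uniform on 0..L under a correct sampler
  for (par in colnames(ranks)) {
    bins <- table(factor(ranks[, par] %/% 5, levels = 0:4))
    pval <- stats::chisq.test(bins)$p.value
    expect_gt(pval, 0.01)
  }
})

test_that("convergence diagnostics detect agreement and disagreement", {
  set.seed(21)
  base <- matrix(rnorm(3000), 1000, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  # identical chains: statistic exactly 1
  dg <- diagnostics(list(base, base, base))
  expect_equal(dg$rhat, rep(1, 3), tolerance = 1e-12)
  # independent chains from the same law: statistic near 1
  ind <- lapply(1:3, function(i) matrix(rnorm(3000), 1000, 3))
  expect_lt(max(diagnostics(ind)$rhat), 1.05)
  # location-shifted chains: flagged
  shift <- list(base, base + 2, base - 2)
  expect_gt(min(diagnostics(shift)$rhat), 1.2)
})
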