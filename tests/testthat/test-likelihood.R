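test_that("longitudinal log-density given b matches the Gaussian oracle", {
  d <- four_pattern_data()
  prm <- tiny_params()
  # single observation exactly at its mean with unit variance
  prm1 <- jm_params(beta = c(9.1 - 0.4, 0.4), alpha_D = prm$alpha_D,
                    gamma_D = c(0, 0), alpha_S = prm$alpha_S,
                    gamma_S = c(0, 0), sigma2_eps = 1, cov = prm$cov)
  ev1 <- data.frame(id = 9L, D_star = 1L, delta_D = 1L, S_star = 1L,
                    delta_S = 1L, z0 = 0)
  lg1 <- data.frame(id = 9L, visit = 1L, y = 9.1)
  d1 <- jm_data(lg1, ev1, d$scheme, d$design)
  expect_equal(longitudinal_loglik_given_b(jm_patient(d1, 9L), prm1,
                                           c(0, 0)),
               -0.5 * log(2 * pi))
  # zero observed rows contribute zero
  ev0 <- ev1; lg0 <- lg1[0, ]
  d0 <- jm_data(lg0, ev0, d$scheme, d$design)
  expect_equal(longitudinal_loglik_given_b(jm_patient(d0, 9L), prm1,
                                           c(1, 2)), 0)
  # random instances against the multivariate normal density
  set.seed(5)
  for (i in 1:4) {
    pt <- patient_i(d, i)
    b <- rnorm(2)
    mu <- drop(pt$X %*% prm$beta) + drop(pt$Z %*% b)
    orc <- mvtnorm::dmvnorm(pt$y, mu, prm$sigma2_eps * diag(pt$n),
                            log = TRUE)
    expect_equal(longitudinal_loglik_given_b(pt, prm, b), orc,
                 tolerance = 1e-12)
  }
  expect_error(longitudinal_loglik_given_b(patient_i(d, 1), prm, c(1, 2, 3)),
               "length")
})

test_that("event sequences reproduce the probit factorization", {
  M <- 4
  sch <- tiny_scheme(M)
  des <- tiny_design(pD = "1", pS = "1")
  mk <- function(D, dD, S, dS) {
    ev <- data.frame(id = 1L, D_star = D, delta_D = dD, S_star = S,
                     delta_S = dS, z0 = 0)
    lg <- data.frame(id = 1L, visit = 1L, y = 10)
    jm_patient(jm_data(lg, ev, sch, des), 1L)
  }
  prm0 <- jm_params(beta = c(10, -0.5), alpha_D = 0, gamma_D = c(0, 0),
                    alpha_S = 0, gamma_S = c(0, 0), sigma2_eps = 4,
                    cov = cov_from_moments(9, 0.4, -0.3))
  # single censored term at lp = 0
  expect_equal(dropout_loglik_given_b(mk(1L, 0L, 1L, 1L), prm0, c(0, 0)),
               log(0.5))
  # survive one visit then drop out, both at lp = 0
  expect_equal(dropout_loglik_given_b(mk(2L, 1L, 2L, 0L), prm0, c(0, 0)),
               log(0.25))
  expect_equal(death_loglik_given_b(mk(2L, 0L, 3L, 1L), prm0, c(0, 0)),
               log(0.125))
})

test_that("event likelihood sums to one over the outcome space at fixed b", {
  # enumerate every observable dropout outcome with C = M for one process
  M <- 5
  sch <- tiny_scheme(M)
  des <- tiny_design()
  prm <- tiny_params()
  b <- c(1.7, -0.6)
  outcomes <- rbind(data.frame(D = 1:M, dD = 1L),
                    data.frame(D = M, dD = 0L))
  tot <- sum(vapply(seq_len(nrow(outcomes)), function(r) {
    ev <- data.frame(id = 1L, D_star = outcomes$D[r],
                     delta_D = outcomes$dD[r], S_star = M, delta_S = 0L,
                     z0 = 0)
    pt <- jm_patient(jm_data(data.frame(id = 1L, visit = 1L, y = 1),
                             ev, sch, des), 1L)
    exp(dropout_loglik_given_b(pt, prm, b))
  }, numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("collect_probit_terms rewrites the event product exactly", {
  d <- simulate_dataset(tiny_config(N = 10, M = 4, p_int = 0.2), seed = 41)
  prm <- tiny_params()
  # completer: K = 2M, all survival signs
  ev <- data.frame(id = 1L, D_star = 4L, delta_D = 0L, S_star = 4L,
                   delta_S = 0L, z0 = 0)
  ptc <- jm_patient(jm_data(data.frame(id = 1L, visit = 1L, y = 1), ev,
                            d$scheme, d$design), 1L)
  tmc <- collect_probit_terms(ptc, prm)
  expect_equal(tmc$K, 8L)
  expect_equal(tmc$sign, rep(1, 8))
  # dropout at 2 then death at 4: terminal terms flip sign
  ev2 <- data.frame(id = 1L, D_star = 2L, delta_D = 1L, S_star = 4L,
                    delta_S = 1L, z0 = 0)
  pt2 <- jm_patient(jm_data(data.frame(id = 1L, visit = 1L, y = 1), ev2,
                            d$scheme, d$design), 1L)
  tm2 <- collect_probit_terms(pt2, prm)
  expect_equal(tm2$K, 6L)
  expect_equal(tm2$sign, c(1, -1, 1, 1, 1, -1))
  # product identity against the literal likelihood at 100 random b
  set.seed(6)
  for (i in 1:10) {
    pt <- patient_i(d, i)
    tm <- collect_probit_terms(pt, prm)
    for (r in 1:10) {
      b <- rnorm(2, sd = 2)
      lhs <- sum(pnorm(tm$sign * (tm$a + drop(tm$C %*% b)), log.p = TRUE))
      rhs <- dropout_loglik_given_b(pt, prm, b) +
        death_loglik_given_b(pt, prm, b)
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  }
})

test_that("the probit-product expectation equals its orthant reduction", {
  # K = 1 degenerate and analytic cases
  t0 <- list(sign = 1, a = 0, C = matrix(0, 1, 2))
  expect_equal(expectation_probit_product(t0, c(0, 0), diag(2)), 0.5)
  set.seed(8)
  for (r in 1:20) {
    s <- sample(c(-1, 1), 1); a <- rnorm(1); cvec <- rnorm(2)
    mu <- rnorm(2); Sb <- random_pd(2)
    t1 <- list(sign = s, a = a, C = matrix(cvec, 1))
    anl <- pnorm(s * (a + sum(cvec * mu)) /
                   sqrt(1 + drop(crossprod(cvec, Sb %*% cvec))))
    expect_equal(expectation_probit_product(t1, mu, Sb), anl,
                 tolerance = 1e-10)
  }
  # K = 6, q = 2 random instance against plain Monte Carlo
  set.seed(9)
  tm <- list(sign = c(1, 1, -1, 1, 1, -1), a = rnorm(6, 0.5),
             C = matrix(rnorm(12, sd = 0.5), 6))
  mu <- c(0.3, -0.2); Sb <- random_pd(2)
  v <- expectation_probit_product(tm, mu, Sb)
  mc <- mc_probit_product(tm, mu, Sb, n = 1e6)
  expect_lt(abs(v - mc$est), 3 * mc$se)
  # Gauss-Hermite evaluation agrees with the orthant evaluation
  vgh <- expectation_probit_product(tm, mu, Sb, method = "gh",
                                    gh_nodes = 30)
  expect_lt(abs(vgh - v), 3e-6)   # within the orthant evaluation tolerance
})

test_that("raising a survival offset never lowers the expectation", {
  set.seed(10)
  tm <- list(sign = c(1, 1, 1, -1), a = c(0.5, 0.2, 0.8, 1.0),
             C = matrix(rnorm(8, sd = 0.4), 4))
  Sb <- random_pd(2)
  base <- expectation_probit_product(tm, c(0, 0), Sb)
  for (k in 1:3) {
    tm2 <- tm; tm2$a[k] <- tm2$a[k] + 0.5
    expect_gte(expectation_probit_product(tm2, c(0, 0), Sb) + 1e-9, base)
  }
})

test_that("marginal likelihood factorizes when associations vanish", {
  prm0 <- tiny_params(gamma_D = c(0, 0), gamma_S = c(0, 0))
  d <- simulate_dataset(tiny_config(N = 8, M = 4, params = prm0,
                                    p_int = 0.15), seed = 43)
  for (i in 1:8) {
    pt <- patient_i(d, i)
    lhs <- marginal_loglik_patient(pt, prm0)
    rhs <- semijm:::long_marginal_and_posterior(pt, prm0)$loglik +
      dropout_loglik_given_b(pt, prm0, c(0, 0)) +
      death_loglik_given_b(pt, prm0, c(0, 0))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("closed-form marginal likelihood matches adaptive quadrature", {
  skip_if_not_installed("statmod")
  prm <- tiny_params()
  d <- simulate_dataset(tiny_config(N = 6, M = 3, p_int = 0.1), seed = 45)
  for (i in 1:6) {
    pt <- patient_i(d, i)
    cf <- marginal_loglik_patient(pt, prm)
    orc <- gh_oracle_loglik(pt, prm)
    expect_equal(cf, orc, tolerance = 1e-4)
  }
})

test_that("marginal likelihood is parameterization invariant", {
  d <- simulate_dataset(tiny_config(N = 6, M = 4), seed = 47)
  Sg <- matrix(c(9, -0.57, -0.57, 0.4), 2)
  p1 <- jm_params(beta = c(10, -0.5), alpha_D = c(1, -0.5),
                  gamma_D = c(0.05, 0.4), alpha_S = c(1.8, -0.8),
                  gamma_S = c(0.1, 0.8), sigma2_eps = 4, cov = Sg)
  p2 <- jm_params(beta = c(10, -0.5), alpha_D = c(1, -0.5),
                  gamma_D = c(0.05, 0.4), alpha_S = c(1.8, -0.8),
                  gamma_S = c(0.1, 0.8), sigma2_eps = 4,
                  cov = recover_cholesky(Sg))
  expect_equal(marginal_loglik_dataset(d, p1), marginal_loglik_dataset(d, p2),
               tolerance = 1e-10)
})

test_that("dataset likelihood is an order-invariant sum of patients", {
  prm <- tiny_params()
  d <- simulate_dataset(tiny_config(N = 7, M = 4, p_int = 0.1), seed = 49)
  per <- marginal_loglik_dataset(d, prm, per_patient = TRUE)
  expect_equal(per$total, sum(per$per_patient$loglik))
  one <- vapply(1:7, function(i)
    marginal_loglik_patient(patient_i(d, i), prm), numeric(1))
  expect_equal(per$per_patient$loglik, one)
  # permute patients
  ord <- c(4, 2, 7, 1, 6, 3, 5)
  d2 <- jm_data(d$long, d$events[ord, ], d$scheme, d$design)
  expect_equal(marginal_loglik_dataset(d2, prm), per$total,
               tolerance = 1e-10)
})
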