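test_that("simulation is deterministic and stable under sample-size growth", {
  cfg <- tiny_config(N = 20, M = 4, p_int = 0.1)
  d1 <- simulate_dataset(cfg, seed = 11)
  d2 <- simulate_dataset(cfg, seed = 11)
  expect_identical(d1$long, d2$long)
  expect_identical(d1$events, d2$events)
  # growing N leaves earlier patients untouched
  cfg2 <- tiny_config(N = 35, M = 4, p_int = 0.1)
  d3 <- simulate_dataset(cfg2, seed = 11)
  expect_identical(d3$events[1:20, ], d1$events)
  expect_identical(d3$long[d3$long$id <= 20, ], d1$long)
})

test_that("with no events and no gaps every patient completes all visits", {
  prm <- tiny_params(alpha_D = c(40, 0), alpha_S = c(40, 0))
  d <- simulate_dataset(tiny_config(N = 25, M = 5, params = prm), seed = 2)
  expect_true(all(d$events$delta_D == 0 & d$events$delta_S == 0))
  expect_true(all(d$events$D_star == 5 & d$events$S_star == 5))
  expect_equal(nrow(d$long), 25 * 5)
})

test_that("observed-data fields are the stated functions of the latents", {
  d <- simulate_dataset(tiny_config(N = 400, M = 4, p_int = 0.05), seed = 3)
  tr <- attr(d, "truth")$latents
  ev <- d$events
  expect_equal(ev$D_star, pmin(tr$D, tr$S, tr$C))
  expect_equal(ev$delta_D, as.integer(tr$D <= tr$C & tr$D <= tr$S))
  expect_equal(ev$S_star, pmin(tr$S, tr$C))
  expect_equal(ev$delta_S, as.integer(tr$S <= tr$C))
  expect_true(all(ev$D_star <= ev$S_star))
  # dropout remains observable before death: pattern (1,1) with D* < S*
  expect_true(any(ev$delta_D == 1 & ev$delta_S == 1 & ev$D_star < ev$S_star))
  # complete outcomes are recomputable from the truth table
  yc <- attr(d, "truth")$y_complete
  ok <- mapply(function(id, v, y) isTRUE(all.equal(yc[id, v], y)),
               d$long$id, d$long$visit, d$long$y)
  expect_true(all(ok))
})

test_that("event-time marginals match the closed form when gamma = 0", {
  prm <- tiny_params(gamma_D = c(0, 0), gamma_S = c(0, 0))
  M <- 3
  N <- 12000
  d <- simulate_dataset(tiny_config(N = N, M = M, params = prm), seed = 13)
  ev <- d$events
  cv <- null_covars(1)
  lpD <- drop(design_matrix(d$design$dropout, cv, 1:M, M) %*% prm$alpha_D)
  lpS <- drop(design_matrix(d$design$death, cv, 1:M, M) %*% prm$alpha_S)
  hD <- 1 - pnorm(lpD); hS <- 1 - pnorm(lpS)
  SD <- cumprod(1 - hD); SS <- cumprod(1 - hS)
  for (j in 1:(M - 1)) {
    # observed dropout at j requires S >= j (death no earlier than j)
    pj <- prod(head(1 - hD, j - 1)) * hD[j] * prod(head(1 - hS, j - 1))
    phat <- mean(ev$D_star == j & ev$delta_D == 1)
    se <- sqrt(pj * (1 - pj) / N)
    expect_lt(abs(phat - pj), 3 * se + 1e-12)
  }
  # death marginal P(S* = j, delta_S = 1) = P(S = j) since C = M
  for (j in 1:(M - 1)) {
    pj <- prod(head(1 - hS, j - 1)) * hS[j]
    phat <- mean(ev$S_star == j & ev$delta_S == 1)
    expect_lt(abs(phat - pj), 3 * sqrt(pj * (1 - pj) / N) + 1e-12)
  }
})

test_that("survival marginals with shared effects match the orthant formula", {
  prm <- tiny_params(gamma_S = c(0, 1.192))
  M <- 5
  N <- 4000
  cfg <- tiny_config(N = N, M = M, params = prm)
  d <- simulate_dataset(cfg, seed = 17)
  tr <- attr(d, "truth")$latents
  cv <- null_covars(1)
  for (j in 2:M) {
    pj <- survival_prob_marginal(prm, d$design, cv, j, M)
    phat <- mean(tr$S >= j)
    expect_lt(abs(phat - pj), 3 * sqrt(pj * (1 - pj) / N))
  }
})

test_that("complete-outcome moments match the mixed-model implied moments", {
  prm <- tiny_params()
  M <- 4
  N <- 8000
  d <- simulate_dataset(tiny_config(N = N, M = M, params = prm), seed = 19)
  yc <- attr(d, "truth")$y_complete
  cv <- null_covars(1)
  X <- design_matrix(d$design$fixed, cv, 1:M, M)
  Z <- design_matrix(d$design$random, cv, 1:M, M)
  mu <- drop(X %*% prm$beta)
  V <- Z %*% tcrossprod(prm$Sigma, Z) + prm$sigma2_eps * diag(M)
  se_mean <- sqrt(diag(V) / N)
  expect_true(all(abs(colMeans(yc) - mu) < 3 * se_mean))
  Vh <- stats::cov(yc)
  # moment SE of a covariance entry is of order sqrt(2) V_jk / sqrt(N)
  tol <- 3 * sqrt((diag(V) %o% diag(V) + V^2) / N)
  expect_true(all(abs(Vh - V) < tol))
})

test_that("the HERS-like configuration reproduces the study conditions", {
  cfg <- hers_like_config(N = 600)
  expect_equal(cfg$scheme$M, 12L)
  expect_equal(cfg$p_int, 0.076)
  expect_equal(cfg$params$gamma_S, c(0.128, 1.192))
  expect_equal(unname(cfg$params$Sigma[1, 1]), 29.120, tolerance = 1e-12)
  d <- simulate_dataset(cfg, seed = 23)
  expect_true(validate_dataset(d))
  # all four observation patterns occur
  expect_equal(nrow(unique(d$events[, c("delta_D", "delta_S")])), 4L)
  # realized intermittent missingness near 7.6% of eligible visits
  tr <- attr(d, "truth")$latents
  sched <- pmin(d$events$D_star, 12)
  death_term <- d$events$delta_S == 1 & tr$S == d$events$D_star &
    d$events$delta_D == 0
  eligible <- sum(sched - death_term)          # visit-1 rows never removed
  deletable <- eligible - d$N
  n_miss <- eligible - nrow(d$long)
  se <- sqrt(0.076 * (1 - 0.076) * deletable)
  expect_lt(abs(n_miss - 0.076 * deletable), 3 * se)
})

test_that("missing-at-random gaps respond to the previous outcome", {
  cfg <- tiny_config(N = 300, M = 6,
                     params = tiny_params(alpha_D = c(40, 0),
                                          alpha_S = c(40, 0)))
  cfg$int_mar <- list(intercept = -1, slope = -0.15)  # low y -> more gaps
  d <- simulate_dataset(cfg, seed = 31)
  tr <- attr(d, "truth")$latents
  n_obs <- as.integer(table(factor(d$long$id, levels = 1:300)))
  expect_gt(sum(6L - n_obs), 0)                 # gaps do occur
  # patients with higher outcome level (larger random intercept) skip fewer
  expect_gt(stats::cor(tr$b1, n_obs), 0.1)
})
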