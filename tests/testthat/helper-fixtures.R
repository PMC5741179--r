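# Shared fixture builders. All datasets are generated in code; sizes are
# kept small so the whole suite stays fast.

# compact one-covariate joint model used across tests
tiny_design <- function(pD = c("1", "visit_frac"), pS = c("1", "visit_frac")) {
  jm_design(fixed = c("1", "visit"), random = c("1", "visit"),
            dropout = pD, death = pS)
}

tiny_params <- function(gamma_D = c(0.05, 0.4), gamma_S = c(0.1, 0.8),
                        alpha_D = c(1.0, -0.5), alpha_S = c(1.8, -0.8)) {
  jm_params(beta = c(10, -0.5), alpha_D = alpha_D, gamma_D = gamma_D,
            alpha_S = alpha_S, gamma_S = gamma_S, sigma2_eps = 4,
            cov = cov_from_moments(9, 0.4, -0.3))
}

tiny_scheme <- function(M) jm_scheme(seq(0, by = 182, length.out = M + 1L))

null_covars <- function(n) data.frame(z0 = rep(0, n))

tiny_config <- function(N = 30, M = 4, params = tiny_params(), p_int = 0,
                        ...) {
  sim_config(N = N, scheme = tiny_scheme(M), design = tiny_design(),
             params = params, covariate_generator = null_covars,
             p_int = p_int, ...)
}

# hand-built four-patient dataset covering the four dropout/death patterns:
# complete, dropout only, death only, dropout then death
four_pattern_data <- function(M = 4) {
  events <- data.frame(
    id = 1:4,
    D_star = c(M, 2L, 3L, 2L),
    delta_D = c(0L, 1L, 0L, 1L),
    S_star = c(M, M, 3L, 3L),
    delta_S = c(0L, 0L, 1L, 1L),
    z0 = 0)
  long <- data.frame(
    id = rep(1:4, times = c(M, 2L, 2L, 2L)),
    visit = c(seq_len(M), 1:2, 1:2, 1:2),
    y = c(10 - 0.5 * seq_len(M), 9.1, 8.2, 7.3, 6.4, 11.0, 10.4))
  jm_data(long, events, tiny_scheme(M), tiny_design())
}

# a patient record straight from a data object, patient i
patient_i <- function(data, i) jm_patient(data, data$events$id[i])

# random positive definite matrix
random_pd <- function(q) {
  A <- matrix(stats::rnorm(q * q), q)
  crossprod(A) + diag(q) * 0.3
}

# plain Monte-Carlo estimate of E[prod Phi(s(a + C b))], b ~ N(mu, Sigma);
# returns estimate and its standard error
mc_probit_product <- function(terms, mu, Sigma, n = 1e6, chunk = 2e5) {
  q <- length(mu)
  C <- matrix(terms$C, ncol = q)
  tot <- 0; tot2 <- 0; m <- 0
  while (m < n) {
    nc <- min(chunk, n - m)
    B <- matrix(stats::rnorm(nc * q), ncol = q) %*% chol(Sigma)
    B <- sweep(B, 2L, mu, "+")
    U <- outer(rep(1, nc), terms$a) + tcrossprod(B, C)
    v <- exp(rowSums(stats::pnorm(t(terms$sign * t(U)), log.p = TRUE)))
    tot <- tot + sum(v); tot2 <- tot2 + sum(v^2); m <- m + nc
  }
  est <- tot / n
  list(est = est, se = sqrt((tot2 / n - est^2) / n))
}

# independent adaptive Gauss-Hermite oracle for the marginal log-likelihood
# of one patient: complete-data likelihood integrated over b on the
# posterior-standardized scale (33-point tensor grid)
gh_oracle_loglik <- function(pt, prm, nodes = 33) {
  gq <- statmod::gauss.quad.prob(nodes, "normal")
  q <- ncol(pt$Z)
  Sg <- prm$Sigma
  if (pt$n > 0) {
    Z <- matrix(pt$Z, nrow = pt$n)
    prec <- crossprod(Z) / prm$sigma2_eps + solve(Sg)
    Sp <- solve(prec)
    mp <- drop(Sp %*% crossprod(Z, pt$y - drop(pt$X %*% prm$beta))) /
      prm$sigma2_eps
  } else { Sp <- Sg; mp <- rep(0, q) }
  L <- t(chol(Sp))
  idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(nodes)), q)))
  tot <- 0
  for (r in seq_len(nrow(idx))) {
    b <- mp + drop(L %*% gq$nodes[idx[r, ]])
    w <- prod(gq$weights[idx[r, ]])
    ll <- longitudinal_loglik_given_b(pt, prm, b) +
      dropout_loglik_given_b(pt, prm, b) +
      death_loglik_given_b(pt, prm, b) +
      mvtnorm::dmvnorm(b, sigma = Sg, log = TRUE) -
      mvtnorm::dmvnorm(b, mp, Sp, log = TRUE)
    tot <- tot + w * exp(ll)
  }
  log(tot)
}
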