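# JAGS engine: the same joint model written as a BUGS program, used as an
# independent cross-check of the Gibbs sampler. Requires the rjags package.

jags_model_string <- function(des) {
  if (des$q != 2L)
    stop("the JAGS engine is implemented for q = 2 (random intercept/slope)")
  paste0('
model {
  for (r in 1:nlong) {
    y[r] ~ dnorm(inprod(X[r, ], beta) +
                 b[idl[r], 1] * Z[r, 1] + b[idl[r], 2] * Z[r, 2], tau_eps)
  }
  for (r in 1:nD) {
    eD[r] ~ dbern(prD[r])
    probit(prD[r]) <- -(inprod(XD[r, ], alphaD) +
                       inprod(WbD[idD[r], ], gammaD))
  }
  for (r in 1:nS) {
    eS[r] ~ dbern(prS[r])
    probit(prS[r]) <- -(inprod(XS[r, ], alphaS) +
                       inprod(WbS[idS[r], ], gammaS))
  }
  for (i in 1:N) {
    b[i, 1] ~ dnorm(0, tau_b1)
    b[i, 2] ~ dnorm(lambda * b[i, 1], tau_b2)
    for (k in 1:qD) { WbD[i, k] <- inprod(WD[k, ], b[i, ]) }
    for (k in 1:qS) { WbS[i, k] <- inprod(WS[k, ], b[i, ]) }
  }
  for (s in 1:p)  { beta[s]   ~ dnorm(0, 1 / v_beta) }
  for (s in 1:pD) { alphaD[s] ~ dnorm(0, 1 / v_assoc) }
  for (s in 1:qD) { gammaD[s] ~ dnorm(0, 1 / v_assoc) }
  for (s in 1:pS) { alphaS[s] ~ dnorm(0, 1 / v_assoc) }
  for (s in 1:qS) { gammaS[s] ~ dnorm(0, 1 / v_assoc) }
  lambda ~ dnorm(0, 1 / v_lambda)
  tau_eps ~ dgamma(ig_eps_a, ig_eps_b)
  tau_b1 ~ dgamma(ig_in_a, ig_in_b)
  tau_b2 ~ dgamma(ig_in_a, ig_in_b)
  sigma2_eps <- 1 / tau_eps
  innov1 <- 1 / tau_b1
  innov2 <- 1 / tau_b2
}')
}

sample_posterior_jags <- function(data, pp, prior, chains, warmup, draws,
                                  thin, chain_seeds) {
  if (!requireNamespace("rjags", quietly = TRUE))
    stop("engine = 'jags' requires the rjags package")
  des <- pp$des
  dat <- list(
    nlong = pp$nlong, y = pp$yv, X = pp$Xl, Z = pp$Zl, idl = pp$lidx,
    nD = pp$dd$n, XD = pp$dd$X, eD = pp$dd$event, idD = pp$dd$idx,
    nS = pp$ss$n, XS = pp$ss$X, eS = pp$ss$event, idS = pp$ss$idx,
    N = pp$N, p = des$p, pD = des$p_D, pS = des$p_S,
    qD = des$q_D, qS = des$q_S, WD = des$W_D, WS = des$W_S,
    v_beta = prior$beta_var, v_assoc = prior$assoc_var,
    v_lambda = prior$lambda_var,
    ig_eps_a = prior$sigma2_eps_ig[1], ig_eps_b = prior$sigma2_eps_ig[2],
    ig_in_a = prior$innov_ig[1], ig_in_b = prior$innov_ig[2])
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = chain_seeds[ch]))
  mod <- rjags::jags.model(textConnection(jags_model_string(des)),
                           data = dat, inits = inits, n.chains = chains,
                           n.adapt = max(200L, warmup %/% 2L), quiet = TRUE)
  stats::update(mod, warmup, progress.bar = "none")
  vars <- c("beta", "alphaD", "gammaD", "alphaS", "gammaS",
            "sigma2_eps", "lambda", "innov1", "innov2")
  sm <- rjags::coda.samples(mod, vars, n.iter = draws, thin = thin,
                            progress.bar = "none")
  # reorder into the package's canonical column layout
  pick <- function(mat, stem, n)
    mat[, if (n == 1L && stem %in% colnames(mat)) stem else
      paste0(stem, "[", seq_len(n), "]"), drop = FALSE]
  reorder <- function(mat) {
    out <- cbind(pick(mat, "beta", des$p),
                 pick(mat, "alphaD", des$p_D), pick(mat, "gammaD", des$q_D),
                 pick(mat, "alphaS", des$p_S), pick(mat, "gammaS", des$q_S),
                 mat[, "sigma2_eps", drop = FALSE],
                 mat[, "lambda", drop = FALSE],
                 mat[, "innov1", drop = FALSE],
                 mat[, "innov2", drop = FALSE])
    colnames(out) <- draw_colnames(des)
    out
  }
  mats <- lapply(sm, function(ch) reorder(as.matrix(ch)))
  dm <- do.call(rbind, mats)
  structure(list(draws = dm,
                 chain = rep(seq_len(chains), each = nrow(mats[[1L]])),
                 design = des, prior = prior, engine = "jags",
                 warmup = warmup, seed = NA_integer_, b_mean = NULL),
            class = "jm_draws")
}
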