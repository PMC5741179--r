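# Bayesian estimation of the joint model.
#
# The sampler works on the complete-data likelihood with the random effects
# b_i retained as latents, so no multivariate normal probabilities are
# needed. Each probit Bernoulli (one per patient per at-risk visit, for
# dropout and for death) is augmented with a truncated normal variable in
# the Albert-Chib fashion; every full conditional is then conjugate:
# Gaussian for the regression blocks (beta; alpha_D, gamma_D; alpha_S,
# gamma_S; the autoregressive parameters lambda of Sigma; the b_i),
# inverse-gamma for the variance components. The b_i update is vectorized
# across patients for the random-intercept-and-slope case (q = 2).

#' Prior specification
#'
#' Defaults: independent `N(0, 100)` on the fixed effects and on the
#' autoregressive parameters `lambda` of the random-effects covariance;
#' weakly informative `N(0, 4)` on the probit-scale hazard coefficients
#' `alpha` and association parameters `gamma`; `inverse-gamma(0.001, 0.001)`
#' on the residual variance and `inverse-gamma(0.01, 1)` on the innovation
#' variances.
#'
#' @param beta_var,lambda_var,assoc_var Prior variances of the normal
#'   priors.
#' @param sigma2_eps_ig,innov_ig Length-2 `(shape, rate)` of the
#'   inverse-gamma priors.
#' @return Object of class `jm_prior`.
#' @export
jm_prior <- function(beta_var = 100, lambda_var = 100, assoc_var = 4,
                     sigma2_eps_ig = c(0.001, 0.001), innov_ig = c(0.01, 1)) {
  stopifnot(beta_var > 0, lambda_var > 0, assoc_var > 0,
            all(sigma2_eps_ig > 0), all(innov_ig > 0))
  structure(list(beta_var = beta_var, lambda_var = lambda_var,
                 assoc_var = assoc_var, sigma2_eps_ig = sigma2_eps_ig,
                 innov_ig = innov_ig),
            class = "jm_prior")
}

# vectorized truncated standard-offset normals, stable in far tails:
# sample w ~ N(mu, 1) conditioned on w > 0 (or w <= 0)
rtnorm_pos <- function(mu) {
  u <- stats::runif(length(mu))
  lt <- log(u) + stats::pnorm(-mu, lower.tail = FALSE, log.p = TRUE)
  mu + stats::qnorm(lt, lower.tail = FALSE, log.p = TRUE)
}
rtnorm_neg <- function(mu) -rtnorm_pos(-mu)

# person-visit expansion of the two event processes
prep_event_rows <- function(data, which = c("dropout", "death")) {
  which <- match.arg(which)
  des <- data$design
  M <- data$scheme$M
  ev <- data$events
  tstar <- if (which == "dropout") ev$D_star else ev$S_star
  delta <- if (which == "dropout") ev$delta_D else ev$delta_S
  terms <- if (which == "dropout") des$dropout else des$death
  idx <- rep(seq_len(nrow(ev)), tstar)
  vis <- unlist(lapply(tstar, seq_len), use.names = FALSE)
  e <- as.integer(vis == tstar[idx] & delta[idx] == 1L)
  X <- design_matrix(terms, ev[idx, , drop = FALSE], vis, M)
  list(X = X, idx = idx, visit = vis, event = e, n = length(idx))
}

prep_gibbs <- function(data) {
  des <- data$design
  if (des$gamma_by_visit)
    stop("the Gibbs sampler supports visit-constant gamma only")
  M <- data$scheme$M
  ev <- data$events
  N <- nrow(ev)
  lidx <- match(data$long$id, ev$id)
  Xl <- design_matrix(des$fixed, ev[lidx, , drop = FALSE], data$long$visit, M)
  Zl <- design_matrix(des$random, ev[lidx, , drop = FALSE], data$long$visit, M)
  yv <- as.numeric(data$long$y)
  dd <- prep_event_rows(data, "dropout")
  ss <- prep_event_rows(data, "death")
  # per-patient constants for the b update
  q <- des$q
  ZtZ <- array(0, c(N, q, q))
  for (k in seq_len(q)) for (l in seq_len(q))
    ZtZ[, k, l] <- rowsum_all(Zl[, k] * Zl[, l], lidx, N)
  list(des = des, M = M, N = N, q = q, ev = ev,
       Xl = Xl, Zl = Zl, yv = yv, lidx = lidx, nlong = length(yv),
       XtX = crossprod(Xl), ZtZ = ZtZ,
       dd = dd, ss = ss,
       nD = tabulate(dd$idx, N), nS = tabulate(ss$idx, N))
}

# rowsum over a fixed number of groups, zeros for absent groups
rowsum_all <- function(x, idx, N) {
  out <- numeric(N)
  if (length(x)) {
    r <- rowsum(x, idx)
    out[as.integer(rownames(r))] <- r[, 1L]
  }
  out
}

# two-stage starting values: least squares for the longitudinal part,
# per-patient ridge estimates of the random effects from the residuals,
# then probit regressions of the event rows on covariates and estimated
# random effects (so the association parameters start near their
# regression estimates rather than at zero)
gibbs_init <- function(pp, prior) {
  q <- pp$q
  beta <- if (pp$nlong) {
    fit <- stats::lm.fit(pp$Xl, pp$yv)
    ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  } else rep(0, pp$des$p)
  s2e <- if (pp$nlong > pp$des$p + 1L)
    max(stats::var(pp$yv - drop(pp$Xl %*% beta)) / 2, 0.1) else 1
  B <- matrix(0, pp$N, q)
  if (pp$nlong) {
    resid <- pp$yv - drop(pp$Xl %*% beta)
    Zres <- vapply(seq_len(q), function(k)
      rowsum_all(pp$Zl[, k] * resid, pp$lidx, pp$N), numeric(pp$N))
    for (i in seq_len(pp$N)) {
      # ridge-regularized per-patient regression of residuals on Z
      P <- pp$ZtZ[i, , ] + diag(q)
      B[i, ] <- drop(solve(P, Zres[i, ]))
    }
  }
  probit_start <- function(rows, Wt, pdim, qdim) {
    if (rows$n == 0L) return(rep(0, pdim + qdim))
    G <- cbind(rows$X, (B %*% Wt)[rows$idx, , drop = FALSE])
    fit <- suppressWarnings(stats::glm.fit(
      G, rows$event, family = stats::binomial(link = "probit")))
    a <- -ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    pmin(pmax(a, -3), 3)
  }
  cb <- if (pp$N >= 2L) stats::cov(B) + diag(1e-3, q) else diag(q)
  cc <- recover_cholesky(cb)
  list(beta = beta,
       thD = probit_start(pp$dd, t(pp$des$W_D), pp$des$p_D, pp$des$q_D),
       thS = probit_start(pp$ss, t(pp$des$W_S), pp$des$p_S, pp$des$q_S),
       s2e = s2e,
       lambda = cc$lambda,
       innov = pmax(cc$innovation_vars, 0.05),
       B = B)
}

draw_mvn_from_precision <- function(mean_rhs, prec) {
  ch <- chol(prec)
  m <- backsolve(ch, backsolve(ch, mean_rhs, transpose = TRUE))
  drop(m + backsolve(ch, stats::rnorm(length(mean_rhs))))
}

# inverse Mills ratio phi(x)/Phi(x), stable across the support
inv_mills <- function(x)
  exp(stats::dnorm(x, log = TRUE) - stats::pnorm(x, log.p = TRUE))

# One Newton-proposal Metropolis-Hastings update of a probit coefficient
# block, targeting p(theta | b, events) with the truncated-normal latents
# integrated out. The proposal is the Gaussian with the Fisher-information
# precision centred at a one-step Newton update from the current point, so
# acceptance is high and successive draws are nearly independent -- this is
# what lets short chains resolve the weakly identified death-model
# associations, where plain data augmentation mixes very slowly.
mh_probit_block <- function(G, s, th, keep, prior_var, n_steps = 2L) {
  off <- if (length(keep) < length(th))
    drop(G[, -keep, drop = FALSE] %*% th[-keep]) else 0
  Gk <- G[, keep, drop = FALSE]
  d <- length(keep)
  # one pass: target log-density, Newton proposal mean and its Cholesky;
  # the proposal precision uses the observed information of the probit
  # log-likelihood, zeta(x)(zeta(x) + x) with x = s * lp, which reuses the
  # same tail probabilities as the target
  eval_point <- function(tk) {
    x <- cap_lp(s * (off + drop(Gk %*% tk)))
    lFx <- stats::pnorm(x, log.p = TRUE)
    zeta <- exp(stats::dnorm(x, log = TRUE) - lFx)
    post <- sum(lFx) - 0.5 * sum(tk^2) / prior_var
    Pm <- crossprod(Gk * sqrt(zeta * (zeta + x))) +
      diag(1 / prior_var, d)
    grad <- drop(crossprod(Gk, s * zeta)) - tk / prior_var
    ch <- chol(Pm)
    list(post = post, ch = ch, ldet = sum(log(diag(ch))),
         mean = tk + backsolve(ch, backsolve(ch, grad, transpose = TRUE)))
  }
  qdens <- function(x, p) {
    r <- drop(p$ch %*% (x - p$mean))
    p$ldet - 0.5 * sum(r^2)
  }
  tk <- th[keep]
  pc <- eval_point(tk)
  for (step in seq_len(n_steps)) {
    tks <- drop(pc$mean + backsolve(pc$ch, stats::rnorm(d)))
    ps <- eval_point(tks)
    la <- ps$post - pc$post + qdens(tk, ps) - qdens(tks, pc)
    if (is.finite(la) && log(stats::runif(1)) < la) {
      tk <- tks
      pc <- ps
    }
  }
  th[keep] <- tk
  th
}

gibbs_chain <- function(pp, prior, n_iter, warmup, thin, init, store_b,
                        fixed = list()) {
  des <- pp$des
  q <- pp$q
  N <- pp$N
  fx <- function(nm) !is.null(fixed[[nm]])
  if (fx("gamma_D")) init$thD[des$p_D + seq_len(des$q_D)] <- fixed$gamma_D
  if (fx("gamma_S")) init$thS[des$p_S + seq_len(des$q_S)] <- fixed$gamma_S
  if (fx("sigma2_eps")) init$s2e <- fixed$sigma2_eps
  if (fx("lambda")) init$lambda <- fixed$lambda
  if (fx("innov")) init$innov <- fixed$innov
  cD <- function(thD) drop(crossprod(des$W_D, thD[des$p_D + seq_len(des$q_D)]))
  cS <- function(thS) drop(crossprod(des$W_S, thS[des$p_S + seq_len(des$q_S)]))

  beta <- init$beta; thD <- init$thD; thS <- init$thS
  s2e <- init$s2e; lambda <- init$lambda; innov <- init$innov
  B <- init$B
  Sigma <- build_sigma(cholesky_cov(lambda, innov))

  n_keep <- (n_iter - warmup) %/% thin
  npar <- length(beta) + length(thD) + length(thS) + 1L +
    length(lambda) + length(innov)
  out <- matrix(NA_real_, n_keep, npar)
  Bsum <- if (store_b) matrix(0, N, q) else NULL
  row <- 0L

  WDt <- t(des$W_D); WSt <- t(des$W_S)
  sD_sign <- 1 - 2 * pp$dd$event
  sS_sign <- 1 - 2 * pp$ss$event
  for (it in seq_len(n_iter)) {
    # --- hazard blocks: MH on p(theta | b, events), latents collapsed ---
    upd_block <- function(rows, Wt, dim_p, dim_q, th, s, gamma_fixed) {
      keep <- if (gamma_fixed) seq_len(dim_p) else seq_len(dim_p + dim_q)
      if (rows$n == 0L) {
        th[keep] <- stats::rnorm(length(keep), 0, sqrt(prior$assoc_var))
        return(th)
      }
      G <- cbind(rows$X, (B %*% Wt)[rows$idx, , drop = FALSE])
      mh_probit_block(G, s, th, keep, prior$assoc_var)
    }
    # draw the truncated-normal latents, then a diffusive conjugate
    # refresh of the block given them, then redraw the latents
    augment_block <- function(rows, Wt, dim_p, dim_q, th, gamma_fixed) {
      if (rows$n == 0L) return(list(th = th, w = numeric(0)))
      G <- cbind(rows$X, (B %*% Wt)[rows$idx, , drop = FALSE])
      draw_w <- function(lp) {
        w <- numeric(rows$n)
        ev1 <- rows$event == 1L
        w[!ev1] <- rtnorm_pos(lp[!ev1])
        w[ev1] <- rtnorm_neg(lp[ev1])
        w
      }
      w <- draw_w(drop(G %*% th))
      keep <- if (gamma_fixed) seq_len(dim_p) else seq_len(dim_p + dim_q)
      off <- if (gamma_fixed)
        drop(G[, -keep, drop = FALSE] %*% th[-keep]) else 0
      Gk <- G[, keep, drop = FALSE]
      prec <- crossprod(Gk) + diag(1 / prior$assoc_var, length(keep))
      th[keep] <- draw_mvn_from_precision(crossprod(Gk, w - off), prec)
      list(th = th, w = draw_w(drop(G %*% th)))
    }
    thD <- upd_block(pp$dd, WDt, des$p_D, des$q_D, thD, sD_sign,
                     fx("gamma_D"))
    thS <- upd_block(pp$ss, WSt, des$p_S, des$q_S, thS, sS_sign,
                     fx("gamma_S"))
    ab <- augment_block(pp$dd, WDt, des$p_D, des$q_D, thD, fx("gamma_D"))
    thD <- ab$th; wDv <- ab$w
    ab <- augment_block(pp$ss, WSt, des$p_S, des$q_S, thS, fx("gamma_S"))
    thS <- ab$th; wSv <- ab$w
    cDv <- cD(thD); cSv <- cS(thS)

    # --- random effects ---
    if (N > 0L) {
      Sinv <- solve(Sigma)
      resid <- pp$yv - drop(pp$Xl %*% beta)
      Zres <- vapply(seq_len(q), function(k)
        rowsum_all(pp$Zl[, k] * resid, pp$lidx, N), numeric(N))
      sD <- rowsum_all(wDv - drop(pp$dd$X %*% thD[seq_len(des$p_D)]),
                       pp$dd$idx, N)
      sS <- rowsum_all(wSv - drop(pp$ss$X %*% thS[seq_len(des$p_S)]),
                       pp$ss$idx, N)
      if (q == 2L) {
        P11 <- Sinv[1, 1] + pp$ZtZ[, 1, 1] / s2e +
          pp$nD * cDv[1]^2 + pp$nS * cSv[1]^2
        P12 <- Sinv[1, 2] + pp$ZtZ[, 1, 2] / s2e +
          pp$nD * cDv[1] * cDv[2] + pp$nS * cSv[1] * cSv[2]
        P22 <- Sinv[2, 2] + pp$ZtZ[, 2, 2] / s2e +
          pp$nD * cDv[2]^2 + pp$nS * cSv[2]^2
        m1 <- Zres[, 1] / s2e + cDv[1] * sD + cSv[1] * sS
        m2 <- Zres[, 2] / s2e + cDv[2] * sD + cSv[2] * sS
        det <- P11 * P22 - P12^2
        V11 <- P22 / det; V22 <- P11 / det; V12 <- -P12 / det
        mu1 <- V11 * m1 + V12 * m2
        mu2 <- V12 * m1 + V22 * m2
        l11 <- sqrt(V11); l21 <- V12 / l11; l22 <- sqrt(pmax(V22 - l21^2, 0))
        e1 <- stats::rnorm(N); e2 <- stats::rnorm(N)
        B[, 1] <- mu1 + l11 * e1
        B[, 2] <- mu2 + l21 * e1 + l22 * e2
      } else {
        ccD <- tcrossprod(cDv); ccS <- tcrossprod(cSv)
        for (i in seq_len(N)) {
          P <- Sinv + pp$ZtZ[i, , ] / s2e + pp$nD[i] * ccD + pp$nS[i] * ccS
          m <- Zres[i, ] / s2e + cDv * sD[i] + cSv * sS[i]
          B[i, ] <- draw_mvn_from_precision(m, P)
        }
      }
    }

    # --- beta ---
    zb <- if (pp$nlong) rowSums(pp$Zl * B[pp$lidx, , drop = FALSE]) else
      numeric(0)
    prec <- pp$XtX / s2e + diag(1 / prior$beta_var, des$p)
    rhs <- if (pp$nlong) crossprod(pp$Xl, pp$yv - zb) / s2e else
      rep(0, des$p)
    beta <- draw_mvn_from_precision(rhs, prec)

    # --- residual variance ---
    if (!fx("sigma2_eps")) {
      ssq <- if (pp$nlong)
        sum((pp$yv - drop(pp$Xl %*% beta) - zb)^2) else 0
      s2e <- 1 / stats::rgamma(1, prior$sigma2_eps_ig[1] + pp$nlong / 2,
                               prior$sigma2_eps_ig[2] + ssq / 2)
    }

    # --- covariance of the random effects via sequential regressions ---
    if (!fx("innov"))
      innov[1] <- 1 / stats::rgamma(1, prior$innov_ig[1] + N / 2,
                                    prior$innov_ig[2] + sum(B[, 1]^2) / 2)
    if (q > 1L) {
      pos <- 1L
      for (k in 2:q) {
        Xk <- B[, seq_len(k - 1L), drop = FALSE]
        if (!fx("lambda")) {
          prec <- crossprod(Xk) / innov[k] +
            diag(1 / prior$lambda_var, k - 1L)
          lam_k <- draw_mvn_from_precision(crossprod(Xk, B[, k]) / innov[k],
                                           prec)
          lambda[pos + seq_len(k - 1L) - 1L] <- lam_k
        } else lam_k <- lambda[pos + seq_len(k - 1L) - 1L]
        if (!fx("innov")) {
          rss <- sum((B[, k] - drop(Xk %*% lam_k))^2)
          innov[k] <- 1 / stats::rgamma(1, prior$innov_ig[1] + N / 2,
                                        prior$innov_ig[2] + rss / 2)
        }
        pos <- pos + k - 1L
      }
    }
    Sigma <- build_sigma(cholesky_cov(lambda, innov))

    if (it > warmup && (it - warmup) %% thin == 0L) {
      row <- row + 1L
      out[row, ] <- c(beta, thD, thS, s2e, lambda, innov)
      if (store_b) Bsum <- Bsum + B
    }
  }
  list(draws = out, b_mean = if (store_b) Bsum / max(row, 1L) else NULL)
}

# thin wrapper marshalling the prepared data into the compiled sampler
gibbs_chain_cpp <- function(pp, prior, n_iter, warmup, thin, init, store_b,
                            fixed = list()) {
  fx <- function(nm) !is.null(fixed[[nm]])
  if (fx("gamma_D"))
    init$thD[pp$des$p_D + seq_len(pp$des$q_D)] <- fixed$gamma_D
  if (fx("gamma_S"))
    init$thS[pp$des$p_S + seq_len(pp$des$q_S)] <- fixed$gamma_S
  if (fx("sigma2_eps")) init$s2e <- fixed$sigma2_eps
  if (fx("lambda")) init$lambda <- fixed$lambda
  if (fx("innov")) init$innov <- fixed$innov
  res <- .gibbs_run_cpp(
    Xl = pp$Xl, Zl = pp$Zl, yv = pp$yv, lidx = as.integer(pp$lidx),
    XD = pp$dd$X, idxD = as.integer(pp$dd$idx),
    eD = as.integer(pp$dd$event),
    XS = pp$ss$X, idxS = as.integer(pp$ss$idx),
    eS = as.integer(pp$ss$event),
    WD = pp$des$W_D, WS = pp$des$W_S, N = pp$N,
    prior = unclass(prior),
    init = init[c("beta", "thD", "thS", "s2e", "lambda", "innov", "B")],
    fixed = list(gamma_D = fx("gamma_D"), gamma_S = fx("gamma_S"),
                 sigma2_eps = fx("sigma2_eps"), lambda = fx("lambda"),
                 innov = fx("innov")),
    n_iter = n_iter, warmup = warmup, thin = thin, mh_steps = 2L,
    store_b = store_b)
  list(draws = res$draws, b_mean = res$b_mean)
}

draw_colnames <- function(des) {
  c(paste0("beta.", des$fixed),
    paste0("alphaD.", des$dropout), paste0("gammaD.", seq_len(des$q_D)),
    paste0("alphaS.", des$death), paste0("gammaS.", seq_len(des$q_S)),
    "sigma2_eps",
    if (des$q > 1L) paste0("lambda.", seq_len(des$q * (des$q - 1L) / 2L)),
    paste0("innov.", seq_len(des$q)))
}

#' Sample the joint-model posterior
#'
#' Targets the posterior of all joint-model parameters under [jm_prior()]
#' priors, with the per-patient random effects retained as latent variables.
#' The default engine is a conjugate Gibbs sampler with truncated-normal
#' augmentation of the probit hazard contributions; `engine = "jags"` runs
#' the same model in JAGS (requires the rjags package) and is intended as an
#' independent cross-check.
#'
#' @param data A [jm_data()].
#' @param prior A [jm_prior()].
#' @param chains Number of chains (run sequentially with distinct seeds and
#'   dispersed starting values).
#' @param warmup Burn-in iterations per chain.
#' @param draws Retained iterations per chain (before thinning).
#' @param thin Thinning interval.
#' @param seed Integer seed; the run is reproducible given `seed`.
#' @param engine `"gibbs"` (default) or `"jags"`.
#' @param store_b If `TRUE`, also return the posterior mean of each
#'   patient's random effects.
#' @param fixed Optional named list of parameters held fixed at given
#'   values instead of being sampled; any of `gamma_D`, `gamma_S`,
#'   `sigma2_eps`, `lambda`, `innov`. Useful for conditional (reduced)
#'   models and for validation against conjugate closed forms.
#' @param impl `"cpp"` (default) runs the compiled sampler; `"r"` runs the
#'   pure-R reference implementation of the same algorithm (slower, used
#'   for cross-validation).
#' @return Object of class `jm_draws`: draw matrix with one column per
#'   parameter (natural scale: `sigma2_eps`, `lambda.*`, `innov.*`), chain
#'   labels, the design, and optionally `b_mean`.
#' @export
sample_posterior <- function(data, prior = jm_prior(), chains = 3L,
                             warmup = 1000L, draws = 2000L, thin = 1L,
                             seed = 1L, engine = c("gibbs", "jags"),
                             store_b = FALSE, fixed = list(),
                             impl = c("cpp", "r")) {
  engine <- match.arg(engine)
  impl <- match.arg(impl)
  stopifnot(inherits(data, "jm_data"), inherits(prior, "jm_prior"))
  bad <- setdiff(names(fixed), c("gamma_D", "gamma_S", "sigma2_eps",
                                 "lambda", "innov"))
  if (length(bad)) stop("cannot fix parameter(s): ",
                        paste(bad, collapse = ", "))
  if (length(fixed) && engine == "jags")
    stop("fixed parameters are supported by the gibbs engine only")
  pp <- prep_gibbs(data)
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  if (engine == "jags")
    return(sample_posterior_jags(data, pp, prior, chains, warmup, draws,
                                 thin, chain_seeds))
  base_init <- gibbs_init(pp, prior)
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    init <- base_init
    if (ch > 1L) {   # dispersed starts around the two-stage estimates,
                     # scaled to a plausible posterior spread
      init$beta <- init$beta + stats::rnorm(length(init$beta), 0, 0.5)
      init$thD <- init$thD + stats::rnorm(length(init$thD), 0, 0.2)
      init$thS <- init$thS + stats::rnorm(length(init$thS), 0, 0.2)
      init$s2e <- init$s2e * exp(stats::rnorm(1, 0, 0.3))
      init$innov <- init$innov * exp(stats::rnorm(pp$q, 0, 0.3))
    }
    res[[ch]] <- if (impl == "cpp")
      gibbs_chain_cpp(pp, prior, warmup + draws, warmup, thin, init,
                      store_b, fixed)
    else gibbs_chain(pp, prior, warmup + draws, warmup, thin, init,
                     store_b, fixed)
  }
  dm <- do.call(rbind, lapply(res, `[[`, "draws"))
  colnames(dm) <- draw_colnames(pp$des)
  structure(list(draws = dm,
                 chain = rep(seq_len(chains), each = nrow(res[[1]]$draws)),
                 design = pp$des, prior = prior, engine = engine,
                 warmup = warmup, seed = seed,
                 b_mean = if (store_b)
                   Reduce(`+`, lapply(res, `[[`, "b_mean")) / chains),
            class = "jm_draws")
}

#' @export
print.jm_draws <- function(x, ...) {
  cat("Joint-model posterior draws:", nrow(x$draws), "draws,",
      length(unique(x$chain)), "chain(s), engine =", x$engine, "\n")
  print(utils::head(summary(x), 12L))
  invisible(x)
}

#' Posterior summary table
#'
#' Posterior mean, SD and central 95% interval per parameter, plus the
#' derived variance/correlation summaries of the random-effects covariance.
#'
#' @param object A `jm_draws` object.
#' @param ... Unused.
#' @return Data frame with one row per parameter.
#' @export
summary.jm_draws <- function(object, ...) {
  dm <- object$draws
  dm <- cbind(dm, derived_sigma_draws(object))
  data.frame(
    parameter = colnames(dm),
    mean = colMeans(dm),
    sd = apply(dm, 2L, stats::sd),
    q2.5 = apply(dm, 2L, stats::quantile, 0.025),
    q97.5 = apply(dm, 2L, stats::quantile, 0.975),
    row.names = NULL)
}

derived_sigma_draws <- function(object) {
  des <- object$design
  q <- des$q
  if (q != 2L) return(NULL)
  lam <- object$draws[, "lambda.1"]
  i1 <- object$draws[, "innov.1"]; i2 <- object$draws[, "innov.2"]
  v1 <- i1
  v2 <- lam^2 * i1 + i2
  cv <- lam * i1
  cbind(var_b1 = v1, var_b2 = v2, cov_b12 = cv,
        corr_b12 = cv / sqrt(v1 * v2))
}

# one jm_params per (possibly thinned) draw
as_param_draws <- function(object, thin = 1L) {
  stopifnot(inherits(object, "jm_draws"))
  des <- object$design
  dm <- object$draws[seq(1L, nrow(object$draws), by = thin), , drop = FALSE]
  p <- des$p; pD <- des$p_D; qD <- des$q_D; pS <- des$p_S; qS <- des$q_S
  q <- des$q; nl <- q * (q - 1L) / 2L
  apply(dm, 1L, function(r) {
    o <- 0L
    take <- function(n) { v <- unname(r[o + seq_len(n)]); o <<- o + n; v }
    beta <- take(p); aD <- take(pD); gD <- take(qD)
    aS <- take(pS); gS <- take(qS); s2 <- take(1L)
    lam <- take(nl); innov <- take(q)
    jm_params(beta = beta, alpha_D = aD, gamma_D = gD, alpha_S = aS,
              gamma_S = gS, sigma2_eps = s2,
              cov = cholesky_cov(lam, innov))
  }, simplify = FALSE)
}

#' Convergence diagnostics
#'
#' Potential scale reduction factors (Gelman-Rubin) computed across chains
#' and effective sample sizes. Identical chains give a statistic of 1;
#' values well above 1 (conventionally 1.1 or 1.2) flag non-convergence.
#'
#' @param draws A `jm_draws` object, or a list of draw matrices (one per
#'   chain, equal dimensions).
#' @return Data frame with columns `parameter`, `rhat`, `n_eff`.
#' @export
diagnostics <- function(draws) {
  if (inherits(draws, "jm_draws")) {
    chains <- lapply(split(seq_len(nrow(draws$draws)), draws$chain),
                     function(ix) draws$draws[ix, , drop = FALSE])
  } else if (is.list(draws)) {
    chains <- lapply(draws, as.matrix)
  } else stop("draws must be a jm_draws object or a list of matrices")
  m <- length(chains)
  n <- nrow(chains[[1L]])
  pars <- colnames(chains[[1L]])
  if (is.null(pars)) pars <- paste0("par", seq_len(ncol(chains[[1L]])))
  rhat <- vapply(seq_along(pars), function(jp) {
    x <- vapply(chains, function(cm) cm[, jp], numeric(n))
    if (m < 2L) return(NA_real_)
    W <- mean(apply(x, 2L, stats::var))
    Bn <- n * stats::var(colMeans(x))
    if (W == 0) return(1)
    max(1, sqrt(((n - 1) / n * W + Bn / n) / W))
  }, numeric(1))
  neff <- vapply(seq_along(pars), function(jp) {
    sum(vapply(chains, function(cm)
      as.numeric(coda::effectiveSize(cm[, jp])), numeric(1)))
  }, numeric(1))
  data.frame(parameter = pars, rhat = rhat, n_eff = neff)
}
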