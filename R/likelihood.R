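# Complete-data likelihood factors and their closed-form marginalization.
#
# Given the random effects b, the three factors of a patient's likelihood
# are (i) a Gaussian density for the observed longitudinal rows, and
# (ii)/(iii) products of probit terms for the dropout and death sequences.
# Writing 1 - Phi(x) = Phi(-x), the two event factors together form a
# product of K = D* + S* terms Phi(s_k (a_k + c_k' b)). Introducing iid
# standard normal epsilon_k with Phi(t) = P(epsilon_k <= t) and
# marginalizing b ~ N(mu, Sigma_b) turns the expectation of the product
# into a single K-dimensional normal probability with upper limits
# u_k = s_k (a_k + c_k' mu) and covariance I_K + A Sigma_b A', where row k
# of A is s_k c_k'. The marginal likelihood is then the Gaussian marginal
# of the longitudinal rows times that probability evaluated under the
# posterior law of b given those rows.

# linear predictors are capped here before any non-log-domain use;
# pnorm(log.p = TRUE) keeps everything finite well beyond this range
.lp_cap <- 37.5

cap_lp <- function(x) pmin(pmax(x, -.lp_cap), .lp_cap)

#' Discrete-time probit hazard
#'
#' `1 - pnorm(lp)`: the event probability at a visit given being at risk.
#' A larger linear predictor means a lower hazard.
#'
#' @param linear_predictor Numeric vector.
#' @return Hazard probabilities in `(0, 1)`.
#' @export
probit_hazard <- function(linear_predictor) {
  stats::pnorm(cap_lp(linear_predictor), lower.tail = FALSE)
}

#' Longitudinal log-likelihood given the random effects
#'
#' Gaussian log-density of the observed outcome rows with mean
#' `X beta + Z b` and covariance `sigma2_eps * I`; intermittent gaps are
#' simply absent rows. Zero observed rows give 0.
#'
#' @param patient A [jm_patient()].
#' @param params A [jm_params()].
#' @param b Numeric vector of random effects (length `q`).
#' @return Log-density (scalar).
#' @export
longitudinal_loglik_given_b <- function(patient, params, b) {
  n <- patient$n
  if (n == 0L) return(0)
  if (length(b) != ncol(patient$Z))
    stop("b has length ", length(b), ", expected ", ncol(patient$Z))
  mu <- drop(patient$X %*% params$beta) + drop(patient$Z %*% b)
  sum(stats::dnorm(patient$y, mu, sqrt(params$sigma2_eps), log = TRUE))
}

# shared worker for the two event sequences
event_loglik_given_b <- function(Xmat, alpha, gamma, W, tstar, delta, b) {
  lp <- drop(Xmat %*% alpha)
  for (j in seq_len(tstar))
    lp[j] <- lp[j] + sum((W %*% b) * gamma_at(gamma, j))
  lp <- cap_lp(lp)
  ll <- 0
  if (tstar > 1L)
    ll <- sum(stats::pnorm(lp[seq_len(tstar - 1L)], log.p = TRUE))
  term <- if (delta == 1L)
    stats::pnorm(lp[tstar], lower.tail = FALSE, log.p = TRUE)
  else stats::pnorm(lp[tstar], log.p = TRUE)
  ll + term
}

#' Dropout log-likelihood given the random effects
#'
#' Discrete-time probit sequence for the observed dropout data
#' `(D_star, delta_D)`: survival factors `Phi(lp_j)` for `j < D_star` and a
#' terminal factor that is the hazard `1 - Phi(lp)` if dropout was observed
#' and a further survival factor otherwise.
#'
#' @inheritParams longitudinal_loglik_given_b
#' @return Log-probability in `(-Inf, 0]`.
#' @export
dropout_loglik_given_b <- function(patient, params, b) {
  des <- patient$design
  event_loglik_given_b(patient$XD, params$alpha_D, params$gamma_D,
                       des$W_D, patient$D_star, patient$delta_D, b)
}

#' Death log-likelihood given the random effects
#'
#' As [dropout_loglik_given_b()] for the observed death data
#' `(S_star, delta_S)`.
#'
#' @inheritParams longitudinal_loglik_given_b
#' @return Log-probability in `(-Inf, 0]`.
#' @export
death_loglik_given_b <- function(patient, params, b) {
  des <- patient$design
  event_loglik_given_b(patient$XS, params$alpha_S, params$gamma_S,
                       des$W_S, patient$S_star, patient$delta_S, b)
}

#' Collect the signed probit factors of the event likelihood
#'
#' Rewrites the product of the dropout and death likelihood factors given
#' `b` as `prod_k Phi(s_k (a_k + c_k' b))`: each process contributes one
#' term per visit up to its observed time, with sign `-1` exactly for an
#' observed terminal event (using `1 - Phi(x) = Phi(-x)`).
#'
#' @inheritParams longitudinal_loglik_given_b
#' @return An object of class `probit_terms`: list with `sign` (length `K`),
#'   `a` (length `K`) and `C` (`K x q` matrix), `K = D_star + S_star`.
#' @export
collect_probit_terms <- function(patient, params) {
  des <- patient$design
  q <- des$q
  one <- function(Xmat, alpha, gamma, W, tstar, delta) {
    a <- drop(Xmat %*% alpha)
    C <- t(vapply(seq_len(tstar),
                  function(j) drop(crossprod(W, gamma_at(gamma, j))),
                  numeric(q)))
    s <- rep(1, tstar)
    if (delta == 1L) s[tstar] <- -1
    list(sign = s, a = a, C = matrix(C, nrow = tstar))
  }
  d <- one(patient$XD, params$alpha_D, params$gamma_D, des$W_D,
           patient$D_star, patient$delta_D)
  s <- one(patient$XS, params$alpha_S, params$gamma_S, des$W_S,
           patient$S_star, patient$delta_S)
  structure(list(sign = c(d$sign, s$sign), a = c(d$a, s$a),
                 C = rbind(d$C, s$C), K = patient$D_star + patient$S_star),
            class = "probit_terms")
}

#' Expectation of a product of probit terms over Gaussian random effects
#'
#' Computes `E[prod_k Phi(s_k (a_k + c_k' b))]` for `b ~ N(mean, cov)`
#' exactly, as the `K`-dimensional normal probability with upper limits
#' `u_k = s_k (a_k + c_k' mean)` and covariance `I_K + A cov A'` where row
#' `k` of `A` is `s_k c_k'`. When no term loads on `b` the product
#' factorizes into univariate probabilities.
#'
#' @param terms A `probit_terms` object from [collect_probit_terms()], or a
#'   list with elements `sign`, `a`, `C`.
#' @param mean Mean vector of the random effects.
#' @param cov Covariance matrix of the random effects.
#' @param method `"orthant"` (default): the exact `K`-dimensional normal
#'   probability via the Genz algorithm. `"gh"`: tensor Gauss-Hermite
#'   quadrature over the `q`-dimensional random-effects space, which is
#'   smooth in the parameters and much faster for `q <= 3`; used by the
#'   likelihood optimizer.
#' @param gh_nodes Quadrature nodes per dimension for `method = "gh"`.
#' @return A probability in `[0, 1]`.
#' @export
expectation_probit_product <- function(terms, mean, cov,
                                       method = c("orthant", "gh"),
                                       gh_nodes = 20L) {
  method <- match.arg(method)
  K <- length(terms$a)
  if (K == 0L) return(1)
  C <- matrix(terms$C, nrow = K)
  u <- terms$sign * cap_lp(terms$a + drop(C %*% mean))
  A <- terms$sign * C
  if (max(abs(A)) == 0) return(prod(stats::pnorm(u)))
  if (method == "gh")
    return(gh_probit_product(u, A, as.matrix(cov), gh_nodes))
  Omega <- diag(K) + A %*% tcrossprod(as.matrix(cov), A)
  mvn_prob(u, Omega)
}

# E_{v ~ N(0, I_q)}[ prod_k Phi(u_k + (A L v)_k) ], L = chol(cov)',
# by a tensor product of Gauss-Hermite rules; exactness improves rapidly
# with gh_nodes because the integrand is smooth and log-concave
gh_probit_product <- function(u, A, cov, gh_nodes) {
  g <- gh_tensor_grid(gh_nodes, ncol(A))
  B <- g$grid %*% chol(cov)         # rows: b values at quadrature nodes
  U <- outer(rep(1, nrow(B)), u) + tcrossprod(B, A)
  lp <- rowSums(stats::pnorm(U, log.p = TRUE))
  v <- sum(exp(lp + g$logw))
  min(max(v, 0), 1)
}

# cached tensor grid of nodes and summed log-weights for dimension q
gh_tensor_grid <- function(n, q) {
  key <- paste0(n, ".", q)
  if (!is.null(.gh_cache[[key]])) return(.gh_cache[[key]])
  gh <- gauss_hermite_normal(n)
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), q)))
  out <- list(grid = matrix(gh$nodes[grid], nrow(grid), q),
              logw = rowSums(matrix(log(gh$weights)[grid],
                                    nrow(grid), q)))
  .gh_cache[[key]] <- out
  out
}

# probabilists' Gauss-Hermite rule (expectation against N(0,1)) via the
# Golub-Welsch eigendecomposition of the Jacobi matrix; cached per order
.gh_cache <- new.env(parent = emptyenv())
gauss_hermite_normal <- function(n) {
  key <- as.character(n)
  if (!is.null(.gh_cache[[key]])) return(.gh_cache[[key]])
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1L))
  J[cbind(seq_len(n - 1L), 2:n)] <- off
  J[cbind(2:n, seq_len(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  out <- list(nodes = e$values, weights = e$vectors[1L, ]^2)
  .gh_cache[[key]] <- out
  out
}

# Gaussian marginal of the observed rows + posterior moments of b given them
long_marginal_and_posterior <- function(patient, params,
                                        Sigma_inv = NULL) {
  Sigma <- params$Sigma
  q <- ncol(Sigma)
  n <- patient$n
  if (n == 0L)
    return(list(loglik = 0, mu_post = rep(0, q), Sigma_post = Sigma))
  if (is.null(Sigma_inv)) Sigma_inv <- solve(Sigma)
  Z <- matrix(patient$Z, nrow = n)
  r <- patient$y - drop(patient$X %*% params$beta)
  V <- Z %*% tcrossprod(Sigma, Z) + params$sigma2_eps * diag(n)
  ch <- tryCatch(chol(V), error = function(e)
    stop("marginal covariance not positive definite: ", conditionMessage(e)))
  w <- backsolve(ch, r, transpose = TRUE)
  ll <- -0.5 * n * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(w^2)
  prec <- crossprod(Z) / params$sigma2_eps + Sigma_inv
  Sigma_post <- solve(prec)
  Sigma_post <- (Sigma_post + t(Sigma_post)) / 2
  mu_post <- drop(Sigma_post %*% crossprod(Z, r)) / params$sigma2_eps
  list(loglik = ll, mu_post = mu_post, Sigma_post = Sigma_post)
}

# probit terms assembled without per-visit loops; valid for visit-constant
# gamma (cD = W_D' gamma_D, cS = W_S' gamma_S precomputed by the caller)
probit_terms_fast <- function(patient, params, cD, cS) {
  sD <- rep(1, patient$D_star)
  if (patient$delta_D == 1L) sD[patient$D_star] <- -1
  sS <- rep(1, patient$S_star)
  if (patient$delta_S == 1L) sS[patient$S_star] <- -1
  list(sign = c(sD, sS),
       a = c(drop(patient$XD %*% params$alpha_D),
             drop(patient$XS %*% params$alpha_S)),
       C = rbind(matrix(cD, patient$D_star, length(cD), byrow = TRUE),
                 matrix(cS, patient$S_star, length(cS), byrow = TRUE)),
       K = patient$D_star + patient$S_star)
}

#' Closed-form marginal log-likelihood of one patient
#'
#' Integrates the random effects out of the complete-data likelihood: the
#' Gaussian marginal of the observed longitudinal rows (mean `X beta`,
#' covariance `Z Sigma Z' + sigma2_eps I`) times the expectation of the
#' probit product under the posterior `b | Y^o ~ N(mu_post, Sigma_post)`,
#' evaluated as a single multivariate normal probability of dimension
#' `D_star + S_star`.
#'
#' @inheritParams longitudinal_loglik_given_b
#' @inheritParams expectation_probit_product
#' @return Log-likelihood (scalar).
#' @export
marginal_loglik_patient <- function(patient, params,
                                    method = c("orthant", "gh"),
                                    gh_nodes = 20L) {
  method <- match.arg(method)
  lp <- long_marginal_and_posterior(patient, params)
  terms <- collect_probit_terms(patient, params)
  pr <- expectation_probit_product(terms, lp$mu_post, lp$Sigma_post,
                                   method = method, gh_nodes = gh_nodes)
  lp$loglik + log(max(pr, .Machine$double.xmin))
}

#' Marginal log-likelihood of a dataset
#'
#' Sum of [marginal_loglik_patient()] over all patients; the result does not
#' depend on patient order.
#'
#' @param data A [jm_data()].
#' @param params A [jm_params()].
#' @param per_patient If `TRUE`, also return the per-patient contributions.
#' @inheritParams expectation_probit_product
#' @return The total log-likelihood, or (with `per_patient = TRUE`) a list
#'   with `total` and a data frame `per_patient`.
#' @export
marginal_loglik_dataset <- function(data, params, per_patient = FALSE,
                                    method = c("orthant", "gh"),
                                    gh_nodes = 20L) {
  method <- match.arg(method)
  check_params_design(params, data$design)
  pats <- attr(data, "patients")
  if (is.null(pats)) pats <- patient_list(data)
  des <- data$design
  Sigma_inv <- solve(params$Sigma)
  const_gamma <- !is.matrix(params$gamma_D) && !is.matrix(params$gamma_S)
  cD <- if (const_gamma) drop(crossprod(des$W_D, params$gamma_D))
  cS <- if (const_gamma) drop(crossprod(des$W_S, params$gamma_S))
  if (const_gamma && !per_patient && max(abs(c(cD, cS))) == 0)
    return(loglik_dataset_nogamma(data, params))
  ll <- vapply(pats, function(pt) {
    lp <- long_marginal_and_posterior(pt, params, Sigma_inv)
    tm <- if (const_gamma) probit_terms_fast(pt, params, cD, cS) else
      collect_probit_terms(pt, params)
    pr <- expectation_probit_product(tm, lp$mu_post, lp$Sigma_post,
                                     method = method, gh_nodes = gh_nodes)
    lp$loglik + log(max(pr, .Machine$double.xmin))
  }, numeric(1))
  if (per_patient)
    list(total = sum(ll),
         per_patient = data.frame(id = data$events$id, loglik = ll))
  else sum(ll)
}

# cache per-patient design matrices on the dataset (used by fitters)
with_patient_cache <- function(data) {
  if (is.null(attr(data, "patients")))
    attr(data, "patients") <- patient_list(data)
  if (is.null(attr(data, "nogamma_cache")))
    attr(data, "nogamma_cache") <- build_nogamma_cache(data)
  data
}

# Vectorized evaluation for the no-association case (gamma = 0, as in the
# ignorable submodel and in profile fits with the associations frozen):
# the event factors no longer involve b, so they reduce to one batched
# probit regression log-likelihood, and the Gaussian marginals are shared
# across patients with identical visit patterns and covariates.
build_nogamma_cache <- function(data) {
  dd <- prep_event_rows(data, "dropout")
  ss <- prep_event_rows(data, "death")
  ev <- data$events
  pats <- attr(data, "patients")
  if (is.null(pats)) pats <- patient_list(data)
  covcols <- setdiff(names(ev),
                     c("id", "D_star", "delta_D", "S_star", "delta_S"))
  key <- vapply(seq_along(pats), function(i)
    paste(c(pats[[i]]$visits, "|",
            unlist(ev[i, covcols, drop = FALSE])), collapse = ","),
    character(1))
  groups <- lapply(split(seq_along(pats), key), function(ix) {
    pt <- pats[[ix[1L]]]
    list(n = pt$n, X = matrix(pt$X, nrow = pt$n),
         Z = matrix(pt$Z, nrow = pt$n),
         Y = matrix(vapply(pats[ix], function(p) p$y, numeric(pt$n)),
                    nrow = pt$n))
  })
  list(dsign = 1 - 2 * dd$event, dX = dd$X,
       ssign = 1 - 2 * ss$event, sX = ss$X,
       groups = groups)
}

loglik_dataset_nogamma <- function(data, params) {
  fc <- attr(data, "nogamma_cache")
  if (is.null(fc)) fc <- build_nogamma_cache(data)
  ll <- sum(stats::pnorm(fc$dsign * cap_lp(drop(fc$dX %*% params$alpha_D)),
                         log.p = TRUE)) +
    sum(stats::pnorm(fc$ssign * cap_lp(drop(fc$sX %*% params$alpha_S)),
                     log.p = TRUE))
  Sigma <- params$Sigma
  for (g in fc$groups) {
    if (g$n == 0L) next
    V <- g$Z %*% tcrossprod(Sigma, g$Z) + params$sigma2_eps * diag(g$n)
    ch <- chol(V)
    R <- g$Y - drop(g$X %*% params$beta)
    W <- backsolve(ch, R, transpose = TRUE)
    ll <- ll + ncol(R) * (-0.5 * g$n * log(2 * pi) - sum(log(diag(ch)))) -
      0.5 * sum(W^2)
  }
  ll
}
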