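# Mortal-cohort (partly conditional) mean profiles.
#
# Conditioning the Gaussian random effects on survival to visit j turns
# their law into a closed skew-normal distribution: the selection event
# "alive at visit j" is the intersection of j-1 probit survival factors.
# With u_k = x_S,ik' alpha_S and row k of A equal to (W_S,ik)' gamma_S for
# k = 1, ..., j-1, the survival probability is Phi_{j-1}(u; I + A Sigma A')
# and the conditional mean of b is Sigma A' times the gradient of
# log Phi_{j-1} at u. The partly conditional outcome profile then follows
# by plugging E(b | alive) into the longitudinal mean.

# terms of the survival selection event for one covariate pattern:
# visits 1..j-1 by default, 1..j with alive_through = TRUE
death_survival_terms <- function(params, design, covars, j, M,
                                 alive_through = FALSE) {
  upto <- if (alive_through) j else j - 1L
  if (upto < 1L)
    return(list(sign = numeric(0), a = numeric(0),
                C = matrix(0, 0L, design$q)))
  XS <- design_matrix(design$death, covars, seq_len(upto), M)
  a <- drop(XS %*% params$alpha_S)
  C <- t(vapply(seq_len(upto),
                function(k) drop(crossprod(design$W_S,
                                           gamma_at(params$gamma_S, k))),
                numeric(design$q)))
  list(sign = rep(1, upto), a = a, C = matrix(C, nrow = upto))
}

#' Marginal probability of being alive at a visit
#'
#' `P(S >= j | x)` after integrating the random effects out: the
#' multivariate normal probability of surviving the death hazards at visits
#' `1..j-1` (or `1..j` with `alive_through = TRUE`). `j = 1` gives 1.
#'
#' @param params A [jm_params()].
#' @param design A [jm_design()].
#' @param covars One-row data frame with the covariate pattern.
#' @param j Visit number (scalar, `1..M`).
#' @param M Number of scheduled visits.
#' @param alive_through If `TRUE`, "alive at j" additionally includes
#'   surviving the visit-`j` hazard itself.
#' @return A probability.
#' @export
survival_prob_marginal <- function(params, design, covars, j, M,
                                   alive_through = FALSE) {
  stopifnot(j >= 1L, j <= M)
  tm <- death_survival_terms(params, design, covars, j, M, alive_through)
  expectation_probit_product(tm, rep(0, design$q), params$Sigma)
}

#' Conditional mean of the random effects given being alive
#'
#' The mean of the closed skew-normal law of `b` given `S >= j`:
#' `Sigma A' grad log Phi_{j-1}(u; I + A Sigma A')`, each partial derivative
#' of the normal CDF evaluated through its conditional-distribution
#' decomposition. `j = 1` returns the zero vector; so does a model with no
#' association (`gamma_S = 0`), since survival then carries no information
#' about `b`.
#'
#' @inheritParams survival_prob_marginal
#' @return Numeric vector of length `q`.
#' @export
conditional_mean_b_given_alive <- function(params, design, covars, j, M,
                                           alive_through = FALSE) {
  q <- design$q
  tm <- death_survival_terms(params, design, covars, j, M, alive_through)
  K <- length(tm$a)
  if (K == 0L) return(rep(0, q))
  A <- tm$sign * matrix(tm$C, nrow = K)
  if (max(abs(A)) == 0) return(rep(0, q))
  u <- tm$sign * cap_lp(tm$a)
  Sigma <- params$Sigma
  Omega <- diag(K) + A %*% tcrossprod(Sigma, A)
  p <- mvn_prob(u, Omega)
  if (p < 1e-300)
    stop("survival probability underflows at visit ", j,
         "; conditional mean not computable")
  g <- mvn_cdf_grad(u, Omega)
  drop(Sigma %*% crossprod(A, g / p))
}

#' Unconditional and partly-conditional mean profiles
#'
#' For a covariate pattern, computes per visit the unconditional
#' (immortal-cohort) mean `x_ij' beta` and the partly conditional
#' (mortal-cohort) mean `E(Y_ij | S_i >= j) = x_ij' beta +
#' z_ij' E(b | S_i >= j)`, together with the marginal probability of being
#' alive. With a matrix of posterior draws, the profile is computed per draw
#' and summarized by the posterior mean and 2.5%/97.5% bands.
#'
#' @param params A [jm_params()], or a `jm_draws` object / parameter matrix
#'   from [sample_posterior()] for posterior-band profiles.
#' @param design A [jm_design()].
#' @param covars One-row data frame with the covariate pattern.
#' @param visits Integer vector of visits (default `1..M`).
#' @param M Number of scheduled visits.
#' @param alive_through Passed to [conditional_mean_b_given_alive()].
#' @param draw_thin For draw input, keep every `draw_thin`-th draw.
#' @return A data frame of class `jm_profile` with columns `visit`,
#'   `unconditional`, `conditional`, `p_alive` (and, for draws, `*_lo` /
#'   `*_hi` 95% band columns).
#' @export
partly_conditional_profile <- function(params, design, covars,
                                       visits = NULL, M, alive_through = FALSE,
                                       draw_thin = 1L) {
  if (is.null(visits)) visits <- seq_len(M)
  one <- function(prm) {
    X <- design_matrix(design$fixed, covars, visits, M)
    Z <- design_matrix(design$random, covars, visits, M)
    unc <- drop(X %*% prm$beta)
    cond <- unc
    palive <- numeric(length(visits))
    for (k in seq_along(visits)) {
      j <- visits[k]
      eb <- conditional_mean_b_given_alive(prm, design, covars, j, M,
                                           alive_through)
      cond[k] <- unc[k] + sum(Z[k, ] * eb)
      palive[k] <- survival_prob_marginal(prm, design, covars, j, M,
                                          alive_through)
    }
    data.frame(visit = visits, unconditional = unc, conditional = cond,
               p_alive = palive)
  }
  if (inherits(params, "jm_params")) {
    out <- one(params)
  } else {
    draws <- as_param_draws(params)
    keep <- seq(1L, length(draws), by = draw_thin)
    per <- lapply(draws[keep], one)
    arr <- function(col) vapply(per, `[[`, numeric(length(visits)), col)
    qs <- function(m, p) apply(matrix(m, nrow = length(visits)), 1L,
                               stats::quantile, probs = p)
    u <- arr("unconditional"); cnd <- arr("conditional"); pa <- arr("p_alive")
    out <- data.frame(
      visit = visits,
      unconditional = rowMeans(matrix(u, nrow = length(visits))),
      unconditional_lo = qs(u, 0.025), unconditional_hi = qs(u, 0.975),
      conditional = rowMeans(matrix(cnd, nrow = length(visits))),
      conditional_lo = qs(cnd, 0.025), conditional_hi = qs(cnd, 0.975),
      p_alive = rowMeans(matrix(pa, nrow = length(visits))))
  }
  class(out) <- c("jm_profile", "data.frame")
  out
}
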