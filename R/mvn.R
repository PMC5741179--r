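# Multivariate normal probabilities and CDF gradients.
#
# The marginal likelihood and the survivor-conditional moments of the random
# effects both reduce to P(W <= u) for W ~ N(0, Omega). For K > 3 this is
# evaluated by the Genz quasi-Monte-Carlo algorithm (mvtnorm::pmvnorm with
# GenzBretz). That algorithm consumes R's RNG stream, so every call runs
# under a saved/restored .Random.seed with a fixed internal seed: the
# likelihood is then a deterministic function of the parameters, which
# matters for optimizers and for reproducibility. K in {2, 3} uses the
# deterministic TVPACK routine; K <= 1 is closed form.

.mvn_seed <- 170332L

with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Multivariate normal orthant probability
#'
#' Computes `P(W <= upper)` for `W ~ N(0, sigma)`. Deterministic for a given
#' input: low dimensions use closed-form / TVPACK routines and higher
#' dimensions use the Genz quasi-Monte-Carlo algorithm under a fixed
#' internal seed (absolute tolerance `1e-6`).
#'
#' @param upper Numeric vector of upper limits; length 0 returns 1.
#' @param sigma Positive definite covariance matrix.
#' @param abseps Absolute error tolerance for the quasi-Monte-Carlo
#'   algorithm.
#' @return A probability in `[0, 1]`.
#' @export
mvn_prob <- function(upper, sigma, abseps = 1e-6) {
  K <- length(upper)
  if (K == 0L) return(1)
  if (K == 1L) return(stats::pnorm(upper / sqrt(as.numeric(sigma))))
  sigma <- as.matrix(sigma)
  if (K <= 3L) {
    p <- mvtnorm::pmvnorm(upper = upper, sigma = sigma,
                          algorithm = mvtnorm::TVPACK(abseps = abseps))
  } else {
    p <- with_preserved_seed(.mvn_seed,
      mvtnorm::pmvnorm(upper = upper, sigma = sigma,
                       algorithm = mvtnorm::GenzBretz(
                         abseps = abseps, releps = 0,
                         maxpts = max(25000L, 4000L * K))))
  }
  min(max(as.numeric(p), 0), 1)
}

# Gradient of u -> Phi_K(u; Omega).
# dPhi/du_k = phi(u_k; w_kk) * Phi_{K-1}(conditional limits; conditional cov)
mvn_cdf_grad <- function(upper, sigma, abseps = 1e-6) {
  K <- length(upper)
  if (K == 0L) return(numeric(0))
  sigma <- as.matrix(sigma)
  g <- numeric(K)
  for (k in seq_len(K)) {
    wkk <- sigma[k, k]
    dens <- stats::dnorm(upper[k], sd = sqrt(wkk))
    if (K == 1L) {
      g[k] <- dens
    } else {
      skk <- sigma[-k, k]
      cond_u <- upper[-k] - skk * upper[k] / wkk
      cond_s <- sigma[-k, -k, drop = FALSE] - tcrossprod(skk) / wkk
      g[k] <- dens * mvn_prob(cond_u, cond_s, abseps = abseps)
    }
  }
  g
}
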