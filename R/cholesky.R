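#' Modified Cholesky parameterization of the random-effects covariance
#'
#' Parameterizes a `q x q` covariance matrix through generalized
#' autoregressive parameters \eqn{\lambda_{kl}} (the regression of the k-th
#' random effect on its predecessors) and innovation variances
#' \eqn{\sigma^2_k}: with `L` the unit lower-triangular matrix holding
#' \eqn{-\lambda_{kl}} and `G = diag(sigma2_k)`, the decomposition is
#' \eqn{L \Sigma L^T = G}. The only constraint needed for positive
#' definiteness is \eqn{\sigma^2_k > 0}; the \eqn{\lambda_{kl}} are
#' unconstrained reals, which makes the parameterization convenient for
#' unconstrained optimization and for prior specification.
#'
#' @param lambda Numeric vector of the `q(q-1)/2` strictly-lower-triangular
#'   autoregressive parameters, in row-major order
#'   (\eqn{\lambda_{21}, \lambda_{31}, \lambda_{32}, \ldots}); may be
#'   `numeric(0)` for `q = 1`.
#' @param innovation_vars Numeric vector of the `q` positive innovation
#'   variances.
#' @return An object of class `cholesky_cov`.
#' @examples
#' cc <- cholesky_cov(lambda = 0.5, innovation_vars = c(4, 1))
#' build_sigma(cc)   # [[4, 2], [2, 2]]
#' @export
cholesky_cov <- function(lambda = numeric(0), innovation_vars) {
  innovation_vars <- as.numeric(innovation_vars)
  q <- length(innovation_vars)
  if (q < 1L) stop("need at least one innovation variance")
  if (any(!is.finite(innovation_vars)) || any(innovation_vars <= 0))
    stop("innovation variances must be positive")
  lambda <- as.numeric(lambda)
  if (length(lambda) != q * (q - 1L) / 2L)
    stop("lambda must have length q(q-1)/2 = ", q * (q - 1L) / 2L)
  if (any(!is.finite(lambda))) stop("lambda must be finite")
  structure(list(q = q, lambda = lambda, innovation_vars = innovation_vars),
            class = "cholesky_cov")
}

# unit lower-triangular L with -lambda_{kl} below the diagonal
lambda_to_L <- function(cov) {
  q <- cov$q
  L <- diag(q)
  if (q > 1L) {
    pos <- 1L
    for (k in 2:q) for (l in 1:(k - 1L)) {
      L[k, l] <- -cov$lambda[pos]
      pos <- pos + 1L
    }
  }
  L
}

#' Build the covariance matrix from its modified Cholesky parameters
#'
#' @param cov A [cholesky_cov()].
#' @return The implied symmetric positive definite covariance matrix
#'   \eqn{\Sigma = L^{-1} G L^{-T}}.
#' @export
build_sigma <- function(cov) {
  stopifnot(inherits(cov, "cholesky_cov"))
  L <- lambda_to_L(cov)
  Linv <- backsolve(L, diag(cov$q), upper.tri = FALSE)
  S <- Linv %*% (cov$innovation_vars * t(Linv))
  (S + t(S)) / 2
}

#' Recover modified Cholesky parameters from a covariance matrix
#'
#' Inverts [build_sigma()]: computes the generalized autoregressive
#' parameters and innovation variances of a symmetric positive definite
#' matrix, so that `build_sigma(recover_cholesky(S))` reproduces `S`.
#'
#' @param sigma Symmetric positive definite matrix.
#' @return A [cholesky_cov()].
#' @export
recover_cholesky <- function(sigma) {
  sigma <- as.matrix(sigma)
  q <- nrow(sigma)
  if (ncol(sigma) != q || !isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-8)))
    stop("sigma must be a symmetric square matrix")
  for (k in seq_len(q)) {
    if (det(sigma[seq_len(k), seq_len(k), drop = FALSE]) <= 0)
      stop("sigma is not positive definite: leading minor of order ", k,
           " is not positive")
  }
  # sequential regressions of b_k on b_1..b_{k-1}
  lambda <- numeric(0)
  innov <- numeric(q)
  innov[1L] <- sigma[1L, 1L]
  if (q > 1L) {
    for (k in 2:q) {
      idx <- seq_len(k - 1L)
      coefs <- solve(sigma[idx, idx, drop = FALSE], sigma[idx, k])
      lambda <- c(lambda, coefs)
      innov[k] <- sigma[k, k] - sum(coefs * sigma[idx, k])
    }
  }
  cholesky_cov(lambda = lambda, innovation_vars = innov)
}

#' @export
print.cholesky_cov <- function(x, ...) {
  cat("Modified Cholesky covariance, q =", x$q, "\n")
  if (length(x$lambda))
    cat("lambda:", paste(signif(x$lambda, 5), collapse = ", "), "\n")
  cat("innovation variances:",
      paste(signif(x$innovation_vars, 5), collapse = ", "), "\n")
  invisible(x)
}

# coerce either a cholesky_cov or a covariance matrix
as_cholesky_cov <- function(x) {
  if (inherits(x, "cholesky_cov")) x else recover_cholesky(x)
}
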