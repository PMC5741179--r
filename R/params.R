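#' Joint model parameters
#'
#' Collects all unknowns of the joint model: fixed effects `beta` of the
#' longitudinal submodel, hazard regression coefficients `alpha_D`/`alpha_S`,
#' association parameters `gamma_D`/`gamma_S` loading the shared random
#' effects into the two hazards, the residual variance `sigma2_eps`, and the
#' random-effects covariance in its modified Cholesky parameterization.
#'
#' @param beta Numeric vector of fixed effects (length `p`).
#' @param alpha_D,alpha_S Hazard covariate coefficients (lengths `p_D`,
#'   `p_S`).
#' @param gamma_D,gamma_S Association parameters (length `q_D` / `q_S`), or
#'   `M x q` matrices when the design has `gamma_by_visit = TRUE`.
#' @param sigma2_eps Positive residual (measurement-error) variance.
#' @param cov A [cholesky_cov()], or a symmetric positive definite matrix
#'   which is converted via [recover_cholesky()].
#' @return Object of class `jm_params`; element `Sigma` caches the implied
#'   covariance matrix.
#' @examples
#' jm_params(beta = c(15, -0.9), alpha_D = 1, gamma_D = c(0.03, 0.44),
#'           alpha_S = 3.4, gamma_S = c(0.13, 1.19), sigma2_eps = 7.3,
#'           cov = cholesky_cov(-0.04, c(29.1, 0.5)))
#' @export
jm_params <- function(beta, alpha_D, gamma_D, alpha_S, gamma_S,
                      sigma2_eps, cov) {
  if (!is.finite(sigma2_eps) || sigma2_eps <= 0)
    stop("sigma2_eps must be positive")
  cov <- as_cholesky_cov(cov)
  p <- structure(
    list(beta = as.numeric(beta),
         alpha_D = as.numeric(alpha_D),
         gamma_D = if (is.matrix(gamma_D)) gamma_D else as.numeric(gamma_D),
         alpha_S = as.numeric(alpha_S),
         gamma_S = if (is.matrix(gamma_S)) gamma_S else as.numeric(gamma_S),
         sigma2_eps = as.numeric(sigma2_eps),
         cov = cov,
         Sigma = build_sigma(cov)),
    class = "jm_params")
  p
}

#' @export
print.jm_params <- function(x, ...) {
  cat("Joint model parameters\n")
  cat("  beta      :", paste(signif(x$beta, 4), collapse = ", "), "\n")
  cat("  alpha_D   :", paste(signif(x$alpha_D, 4), collapse = ", "), "\n")
  cat("  gamma_D   :", paste(signif(c(x$gamma_D), 4), collapse = ", "), "\n")
  cat("  alpha_S   :", paste(signif(x$alpha_S, 4), collapse = ", "), "\n")
  cat("  gamma_S   :", paste(signif(c(x$gamma_S), 4), collapse = ", "), "\n")
  cat("  sigma2_eps:", signif(x$sigma2_eps, 4), "\n")
  cat("  Sigma     :\n")
  print(signif(x$Sigma, 4))
  invisible(x)
}

check_params_design <- function(params, design) {
  stopifnot(inherits(params, "jm_params"), inherits(design, "jm_design"))
  gd <- if (is.matrix(params$gamma_D)) ncol(params$gamma_D) else
    length(params$gamma_D)
  gs <- if (is.matrix(params$gamma_S)) ncol(params$gamma_S) else
    length(params$gamma_S)
  if (length(params$beta) != design$p ||
      length(params$alpha_D) != design$p_D ||
      length(params$alpha_S) != design$p_S ||
      gd != design$q_D || gs != design$q_S ||
      params$cov$q != design$q)
    stop("parameter dimensions do not match the design")
  invisible(TRUE)
}

# --- unconstrained vectorization for optimization ---------------------------

# order: beta, alpha_D, gamma_D, alpha_S, gamma_S, log sigma2_eps,
#        lambda, log innovation_vars
params_to_vector <- function(params) {
  c(params$beta, params$alpha_D, c(params$gamma_D),
    params$alpha_S, c(params$gamma_S),
    log(params$sigma2_eps),
    params$cov$lambda, log(params$cov$innovation_vars))
}

vector_to_params <- function(theta, template) {
  take <- function(n) {
    if (n == 0L) return(numeric(0))
    v <- theta[seq_len(n)]
    theta <<- theta[-seq_len(n)]
    v
  }
  beta <- take(length(template$beta))
  alpha_D <- take(length(template$alpha_D))
  gamma_D <- take(length(c(template$gamma_D)))
  if (is.matrix(template$gamma_D))
    gamma_D <- matrix(gamma_D, nrow(template$gamma_D))
  alpha_S <- take(length(template$alpha_S))
  gamma_S <- take(length(c(template$gamma_S)))
  if (is.matrix(template$gamma_S))
    gamma_S <- matrix(gamma_S, nrow(template$gamma_S))
  s2 <- exp(take(1L))
  lambda <- take(length(template$cov$lambda))
  innov <- exp(take(length(template$cov$innovation_vars)))
  jm_params(beta, alpha_D, gamma_D, alpha_S, gamma_S, s2,
            cholesky_cov(lambda, innov))
}

param_vector_names <- function(params, design = NULL) {
  nm_or <- function(terms, n, stem)
    if (!is.null(terms) && length(terms) == n) terms else
      paste0(stem, seq_len(n))
  fixed <- if (is.null(design)) NULL else design$fixed
  drop <- if (is.null(design)) NULL else design$dropout
  death <- if (is.null(design)) NULL else design$death
  c(paste0("beta.", nm_or(fixed, length(params$beta), "b")),
    paste0("alphaD.", nm_or(drop, length(params$alpha_D), "a")),
    paste0("gammaD.", seq_along(c(params$gamma_D))),
    paste0("alphaS.", nm_or(death, length(params$alpha_S), "a")),
    paste0("gammaS.", seq_along(c(params$gamma_S))),
    "log_sigma2_eps",
    if (length(params$cov$lambda))
      paste0("lambda.", seq_along(params$cov$lambda)),
    paste0("log_innov.", seq_along(params$cov$innovation_vars)))
}
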