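# Maximum likelihood estimation of the joint model.
#
# The closed-form marginal likelihood (multivariate normal probabilities of
# dimension D* + S* per patient) is maximized over the unconstrained
# parameterization: raw regression coefficients, log variances, raw
# autoregressive parameters of the random-effects covariance. The default
# optimizer is Nelder-Mead with a restart, because the quasi-Monte-Carlo
# noise floor of the normal probabilities (held deterministic by a fixed
# internal seed, but still a plateau at ~1e-6) makes gradient-based methods
# unreliable; Hessian-based standard errors are computed on request and
# flagged when curvature is within an order of magnitude of that floor.

#' Maximum-likelihood fit of the joint model
#'
#' @param data A [jm_data()].
#' @param init Optional [jm_params()] starting value; by default a
#'   method-of-moments start (least squares for the longitudinal part,
#'   probit regressions with `b = 0` for the hazards).
#' @param fixed Optional named numeric vector of parameters (unconstrained
#'   scale, names as in the fit's `par_names`) held fixed, e.g.
#'   `c(gammaD.1 = 0)`.
#' @param control List: `maxit` (default 2000), `reltol` on the
#'   log-likelihood (default 1e-8), `restarts` (default 1), `hessian`
#'   (default FALSE), `trace` (default 0), `method` (`"gh"`, the default
#'   smooth Gauss-Hermite likelihood, or `"orthant"` for the Genz normal-
#'   probability evaluation) and `gh_nodes` (default 20).
#' @return Object of class `jm_mle`: `params` (the MLE), `loglik`,
#'   `convergence` report (iterations, restarts, tolerance met), `monitor`
#'   (accepted log-likelihood trace), `par`, `par_names`, and optionally
#'   `hessian` / `se`.
#' @export
fit_mle <- function(data, init = NULL, fixed = NULL, control = list()) {
  stopifnot(inherits(data, "jm_data"))
  ctl <- utils::modifyList(list(maxit = 2000L, reltol = 1e-8,
                                restarts = 1L, hessian = FALSE, trace = 0L,
                                method = "gh", gh_nodes = 20L),
                           control)
  data <- with_patient_cache(data)
  if (is.null(init)) init <- moment_init_params(data)
  check_params_design(init, data$design)
  template <- init
  nm <- param_vector_names(init, data$design)
  th0 <- stats::setNames(params_to_vector(init), nm)

  fix_idx <- integer(0)
  if (!is.null(fixed)) {
    fix_idx <- match(names(fixed), nm)
    if (anyNA(fix_idx)) stop("unknown fixed parameter name(s): ",
                             paste(names(fixed)[is.na(fix_idx)],
                                   collapse = ", "))
    th0[fix_idx] <- fixed
  }
  free <- setdiff(seq_along(th0), fix_idx)

  monitor <- new.env()
  monitor$trace <- numeric(0)
  negll <- function(th_free) {
    th <- th0
    th[free] <- th_free
    ll <- tryCatch(
      marginal_loglik_dataset(data, vector_to_params(unname(th), template),
                              method = ctl$method, gh_nodes = ctl$gh_nodes),
      error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    if (!length(monitor$trace) || ll > max(monitor$trace))
      monitor$trace <- c(monitor$trace, ll)
    -ll
  }

  v0 <- negll(th0[free])
  if (v0 >= 1e10)
    stop("log-likelihood is not finite at the starting values; supply an ",
         "init based on a method-of-moments LMM fit")

  par <- th0[free]
  counts <- 0L
  val <- v0
  for (r in 0:ctl$restarts) {
    opt <- stats::optim(par, negll, method = "Nelder-Mead",
                        control = list(maxit = ctl$maxit,
                                       reltol = ctl$reltol,
                                       trace = ctl$trace))
    counts <- counts + opt$counts[1L]
    improved <- val - opt$value
    par <- opt$par
    val <- opt$value
    if (r < ctl$restarts && improved < 1e-5) break
  }
  th <- th0
  th[free] <- par
  params <- vector_to_params(unname(th), template)

  out <- list(params = params, loglik = -val,
              par = th, par_names = nm, free = free, control = ctl,
              fixed = fixed,
              template = template, data_design = data$design,
              monitor = monitor$trace,
              convergence = list(iterations = counts,
                                 code = opt$convergence,
                                 tol_met = opt$convergence == 0L,
                                 final_improvement = improved))
  if (isTRUE(ctl$hessian)) {
    H <- stats::optimHess(par, negll)
    se <- rep(NA_real_, length(th))
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (all(ev > 0)) se[free] <- sqrt(diag(solve(H)))
    else warning("Hessian not positive definite; standard errors omitted")
    if (any(is.finite(se)) && min(abs(ev[ev > 0])) < 1e-5 * 10)
      warning("curvature within an order of magnitude of the normal-",
              "probability tolerance; Hessian-based SEs unreliable")
    out$hessian <- H
    out$se <- stats::setNames(se, nm)
  }
  class(out) <- "jm_mle"
  out
}

#' @export
print.jm_mle <- function(x, ...) {
  cat("Joint model MLE: loglik =", format(x$loglik, digits = 8),
      "| iterations =", x$convergence$iterations,
      "| converged =", x$convergence$tol_met, "\n")
  print(x$params)
  invisible(x)
}

# method-of-moments start shared by the fitters
moment_init_params <- function(data) {
  pp <- prep_gibbs(data)
  ini <- gibbs_init(pp, jm_prior())
  q <- pp$q
  innov <- rep(1, q)
  if (pp$nlong) {
    # split the residual variance between the random intercept and noise
    r <- pp$yv - drop(pp$Xl %*% ini$beta)
    innov[1L] <- max(stats::var(r) / 2, 0.05)
    if (q > 1L) innov[2:q] <- 0.1
  }
  jm_params(beta = ini$beta,
            alpha_D = ini$thD[seq_len(pp$des$p_D)],
            gamma_D = rep(0, pp$des$q_D),
            alpha_S = ini$thS[seq_len(pp$des$p_S)],
            gamma_S = rep(0, pp$des$q_S),
            sigma2_eps = max(ini$s2e, 0.05),
            cov = cholesky_cov(rep(0, q * (q - 1L) / 2L), innov))
}

# quadratic smoothing of a profile: fit l ~ a + b t + c t^2, return the
# smoothed maximizer and the likelihood-ratio interval at the given drop
quad_profile_interval <- function(tvals, lvals, drop = stats::qchisq(0.95, 1) / 2) {
  fit <- stats::lm(lvals ~ tvals + I(tvals^2))
  cf <- stats::coef(fit)
  a <- cf[1L]; b <- cf[2L]; cc <- cf[3L]
  if (!is.finite(cc) || cc >= 0)
    return(list(estimate = tvals[which.max(lvals)], lower = NA_real_,
                upper = NA_real_, concave = FALSE, coef = cf))
  tmax <- -b / (2 * cc)
  half <- sqrt(drop / (-cc))
  list(estimate = unname(tmax), lower = unname(tmax - half),
       upper = unname(tmax + half), concave = TRUE, coef = cf)
}

#' Profile-likelihood point estimate and 95% interval
#'
#' Evaluates the profile log-likelihood of one parameter on a grid around
#' the MLE (re-maximizing all other parameters at each grid point), smooths
#' it with a quadratic least-squares fit, and returns the smoothed maximizer
#' together with the likelihood-ratio interval (drop of
#' `qchisq(0.95, 1) / 2`). If the profile is not concave on the grid, the
#' grid is widened once with a warning.
#'
#' @param data A [jm_data()].
#' @param fit A `jm_mle` object from [fit_mle()].
#' @param param Parameter name (see `fit$par_names`) or index.
#' @param grid_size Number of grid points (default 10).
#' @param span Half-width of the grid; defaults to twice the Wald SE when
#'   available, else `0.5 + 0.25 |estimate|`.
#' @param maxit Iteration cap for each inner re-maximization.
#' @return List with `estimate`, `lower`, `upper`, and the profiled `grid`
#'   (data frame of grid value and profile log-likelihood).
#' @export
profile_ci <- function(data, fit, param, grid_size = 10L, span = NULL,
                       maxit = 500L) {
  stopifnot(inherits(fit, "jm_mle"))
  k <- if (is.character(param)) match(param, fit$par_names) else
    as.integer(param)
  if (is.na(k) || k < 1L || k > length(fit$par))
    stop("unknown parameter: ", param)
  est <- fit$par[k]
  if (is.null(span)) {
    span <- if (!is.null(fit$se) && is.finite(fit$se[k])) 2 * fit$se[k] else
      0.5 + 0.25 * abs(est)
  }
  prof_one <- function(val) {
    f <- fit_mle(data, init = vector_to_params(unname(fit$par),
                                               fit$template),
                 fixed = c(stats::setNames(val, fit$par_names[k]),
                           fit$fixed[names(fit$fixed) != fit$par_names[k]]),
                 control = utils::modifyList(
                   fit$control, list(maxit = maxit, restarts = 0L,
                                     hessian = FALSE)))
    f$loglik
  }
  make_grid <- function(s) seq(est - s, est + s, length.out = grid_size)
  tvals <- make_grid(span)
  lvals <- vapply(tvals, prof_one, numeric(1))
  sm <- quad_profile_interval(tvals, lvals)
  if (!sm$concave) {
    warning("profile log-likelihood not concave on the grid; widening")
    tvals <- make_grid(2 * span)
    lvals <- vapply(tvals, prof_one, numeric(1))
    sm <- quad_profile_interval(tvals, lvals)
  }
  list(estimate = sm$estimate, lower = sm$lower, upper = sm$upper,
       parameter = fit$par_names[k],
       grid = data.frame(value = tvals, profile_loglik = lvals))
}

#' Ignorable linear mixed model fit
#'
#' The comparator that treats dropout and death as ignorable: the joint
#' model with both association parameters frozen at zero and the event
#' factors dropped, i.e. an ordinary LMM maximum-likelihood fit of the
#' observed longitudinal rows. The fixed effects are profiled out by
#' generalized least squares at each variance-parameter value.
#'
#' @param data A [jm_data()].
#' @param control List with `maxit` and `reltol` for the Nelder-Mead search
#'   over the variance parameters.
#' @return List of class `jm_lmm`: `beta`, `sigma2_eps`, `cov`
#'   ([cholesky_cov()]), `Sigma`, `loglik`.
#' @export
fit_lmm_ignorable <- function(data, control = list()) {
  ctl <- utils::modifyList(list(maxit = 1000L, reltol = 1e-10), control)
  data <- with_patient_cache(data)
  pats <- attr(data, "patients")
  q <- data$design$q
  p <- data$design$p
  nl <- q * (q - 1L) / 2L

  gls_loglik <- function(vpar) {
    s2 <- exp(vpar[1L])
    cov <- cholesky_cov(vpar[1L + seq_len(nl)],
                        exp(vpar[1L + nl + seq_len(q)]))
    Sigma <- build_sigma(cov)
    XtVX <- matrix(0, p, p); XtVy <- numeric(p)
    pieces <- lapply(pats, function(pt) {
      if (pt$n == 0L) return(NULL)
      Z <- matrix(pt$Z, nrow = pt$n)
      V <- Z %*% tcrossprod(Sigma, Z) + s2 * diag(pt$n)
      ch <- chol(V)
      Xw <- backsolve(ch, pt$X, transpose = TRUE)
      yw <- backsolve(ch, pt$y, transpose = TRUE)
      list(Xw = Xw, yw = yw, ldet = sum(log(diag(ch))), n = pt$n)
    })
    pieces <- Filter(Negate(is.null), pieces)
    Xw <- do.call(rbind, lapply(pieces, `[[`, "Xw"))
    yw <- unlist(lapply(pieces, `[[`, "yw"))
    beta <- drop(solve(crossprod(Xw), crossprod(Xw, yw)))
    rss <- sum((yw - drop(Xw %*% beta))^2)
    ntot <- sum(vapply(pieces, `[[`, numeric(1), "n"))
    ll <- -0.5 * ntot * log(2 * pi) -
      sum(vapply(pieces, `[[`, numeric(1), "ldet")) - 0.5 * rss
    list(loglik = ll, beta = beta)
  }

  init <- moment_init_params(data)
  v0 <- c(log(init$sigma2_eps), init$cov$lambda,
          log(init$cov$innovation_vars))
  opt <- stats::optim(v0, function(v) -gls_loglik(v)$loglik,
                      method = "Nelder-Mead",
                      control = list(maxit = ctl$maxit,
                                     reltol = ctl$reltol))
  best <- gls_loglik(opt$par)
  cov <- cholesky_cov(opt$par[1L + seq_len(nl)],
                      exp(opt$par[1L + nl + seq_len(q)]))
  structure(list(beta = best$beta, sigma2_eps = exp(opt$par[1L]),
                 cov = cov, Sigma = build_sigma(cov),
                 loglik = best$loglik, convergence = opt$convergence),
            class = "jm_lmm")
}

#' @export
print.jm_lmm <- function(x, ...) {
  cat("Ignorable LMM fit: loglik =", format(x$loglik, digits = 8), "\n")
  cat("beta:", paste(signif(x$beta, 4), collapse = ", "), "\n")
  cat("sigma2_eps:", signif(x$sigma2_eps, 4), "\n")
  invisible(x)
}
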