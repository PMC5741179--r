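# Posterior predictive model assessment.
#
# For each posterior draw, replicated observed data are generated from the
# fitted joint model: dropout and death times from the probit hazards,
# a complete longitudinal vector from the linear mixed model, truncated at
# min(D_rep, S_rep, M). The chi-square discrepancy compares (observed or
# replicated) longitudinal rows with their marginal law after integrating
# the random effects out; the posterior predictive probability is the
# fraction of draws in which the replicated statistic exceeds the observed
# one (ties count one half).

# per-patient design matrices over all M visits, stacked (N*M rows)
prep_ppc <- function(data) {
  des <- data$design
  M <- data$scheme$M
  ev <- data$events
  N <- nrow(ev)
  idx <- rep(seq_len(N), each = M)
  vis <- rep(seq_len(M), N)
  evx <- ev[idx, , drop = FALSE]
  list(des = des, M = M, N = N, ids = ev$id,
       X = design_matrix(des$fixed, evx, vis, M),
       Z = design_matrix(des$random, evx, vis, M),
       XD = design_matrix(des$dropout, evx, vis, M),
       XS = design_matrix(des$death, evx, vis, M))
}

# vectorized sequential-Bernoulli event times for all patients; M+1 = never
draw_event_times_vec <- function(lp_mat) {
  N <- nrow(lp_mat); M <- ncol(lp_mat)
  tt <- rep.int(M + 1L, N)
  pending <- rep.int(TRUE, N)
  for (j in seq_len(M)) {
    h <- probit_hazard(lp_mat[, j])
    hit <- pending & (stats::runif(N) < h)
    tt[hit] <- j
    pending <- pending & !hit
  }
  tt
}

lp_matrix <- function(Xh, alpha, B, W, gamma, N, M) {
  lp <- matrix(drop(Xh %*% alpha), N, M, byrow = TRUE)
  if (is.matrix(gamma)) {           # visit-varying association
    for (j in seq_len(M))
      lp[, j] <- lp[, j] + drop(B %*% crossprod(W, gamma[j, ]))
  } else {
    lp <- lp + drop(B %*% crossprod(W, gamma)) # recycled over columns
  }
  lp
}

#' Replicate the observed longitudinal data under one parameter draw
#'
#' For every patient: draw random effects and a complete outcome vector
#' from the longitudinal submodel, dropout and death times from the two
#' probit hazards, and truncate at `min(D_rep, S_rep, M)` (administrative
#' censoring at the final visit; no intermittent missingness). Uses the
#' caller's RNG state.
#'
#' @param params A [jm_params()].
#' @param data A [jm_data()] supplying covariates and design.
#' @param prep Optional cached result of the internal design expansion
#'   (reused across draws by [ppc_probability()]).
#' @return Data frame `id`, `visit`, `y` of replicated observed rows.
#' @export
replicate_observed <- function(params, data, prep = NULL) {
  if (is.null(prep)) prep <- prep_ppc(data)
  des <- prep$des; N <- prep$N; M <- prep$M
  B <- matrix(stats::rnorm(N * des$q), N) %*% chol(params$Sigma)
  ymat <- matrix(drop(prep$X %*% params$beta) +
                   rowSums(prep$Z * B[rep(seq_len(N), each = M), ,
                                      drop = FALSE]),
                 N, M, byrow = TRUE) +
    matrix(stats::rnorm(N * M, sd = sqrt(params$sigma2_eps)), N, M)
  Drep <- draw_event_times_vec(
    lp_matrix(prep$XD, params$alpha_D, B, des$W_D, params$gamma_D, N, M))
  Srep <- draw_event_times_vec(
    lp_matrix(prep$XS, params$alpha_S, B, des$W_S, params$gamma_S, N, M))
  jcut <- pmin(Drep, Srep, M)
  idx <- rep(seq_len(N), jcut)
  vis <- unlist(lapply(jcut, seq_len), use.names = FALSE)
  data.frame(id = prep$ids[idx], visit = vis,
             y = ymat[cbind(idx, vis)])
}

#' Chi-square discrepancy of longitudinal data against the marginal model
#'
#' `sum_i (Y_i - mu_i)' Omega_i^{-1} (Y_i - mu_i) / n_total` with
#' `mu_i = X_i beta` and `Omega_i = Z_i Sigma Z_i' + sigma2_eps I`
#' restricted to patient `i`'s observed visits; `n_total` is the total
#' number of observations. At the generating parameters the statistic has
#' expectation 1.
#'
#' @param long Data frame of longitudinal rows (`id`, `visit`, `y`); the
#'   observed rows of `data` or a replicate from [replicate_observed()].
#' @param data A [jm_data()] supplying covariates and design.
#' @param params A [jm_params()].
#' @return The discrepancy statistic (scalar).
#' @export
chi2_discrepancy <- function(long, data, params) {
  if (nrow(long) == 0L) stop("no longitudinal rows to compare")
  des <- data$design
  M <- data$scheme$M
  ev <- data$events
  ridx <- match(long$id, ev$id)
  if (anyNA(ridx)) stop("replicated rows refer to unknown patient ids")
  X <- design_matrix(des$fixed, ev[ridx, , drop = FALSE], long$visit, M)
  Z <- design_matrix(des$random, ev[ridx, , drop = FALSE], long$visit, M)
  r <- long$y - drop(X %*% params$beta)
  tot <- 0
  for (rows in split(seq_len(nrow(long)), ridx)) {
    Zi <- Z[rows, , drop = FALSE]
    V <- Zi %*% tcrossprod(params$Sigma, Zi) +
      params$sigma2_eps * diag(length(rows))
    w <- backsolve(chol(V), r[rows], transpose = TRUE)
    tot <- tot + sum(w^2)
  }
  tot / nrow(long)
}

#' Posterior predictive probability of the chi-square discrepancy
#'
#' For each retained posterior draw, computes the observed discrepancy and
#' the discrepancy of data replicated under that draw (same parameters on
#' both sides), and returns the fraction of draws in which the replicated
#' statistic exceeds the observed one; exact ties count 0.5. Values near 0
#' or 1 indicate misfit.
#'
#' @param draws A `jm_draws` object from [sample_posterior()], or a list of
#'   [jm_params()].
#' @param data A [jm_data()].
#' @param reps_per_draw Replicated datasets per draw (default 1).
#' @param thin Keep every `thin`-th draw.
#' @param seed Seed for the replication randomness.
#' @return List of class `jm_ppc`: `p`, and the paired statistics
#'   (`observed`, `replicated`).
#' @export
ppc_probability <- function(draws, data, reps_per_draw = 1L, thin = 1L,
                            seed = 1L) {
  plist <- if (inherits(draws, "jm_draws")) as_param_draws(draws, thin) else
    draws
  if (length(plist) < 1L) stop("no posterior draws supplied")
  prep <- prep_ppc(data)
  set.seed(seed)
  obs <- numeric(0)
  rep_ <- numeric(0)
  for (prm in plist) {
    t_obs <- chi2_discrepancy(data$long, data, prm)
    for (r in seq_len(reps_per_draw)) {
      yrep <- replicate_observed(prm, data, prep)
      obs <- c(obs, t_obs)
      rep_ <- c(rep_, chi2_discrepancy(yrep, data, prm))
    }
  }
  p <- mean((rep_ > obs) + 0.5 * (rep_ == obs))
  structure(list(p = p, observed = obs, replicated = rep_), class = "jm_ppc")
}

#' @export
print.jm_ppc <- function(x, ...) {
  cat("Posterior predictive check (chi-square discrepancy)\n")
  cat("  p =", format(x$p, digits = 3), "over", length(x$observed),
      "replicates\n")
  cat("  observed statistic:", format(mean(x$observed), digits = 4),
      " replicated:", format(mean(x$replicated), digits = 4), "\n")
  invisible(x)
}
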