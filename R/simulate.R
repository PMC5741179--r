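# Simulation of HERS-like cohorts from the joint model, with known truth.
#
# Each patient draws random effects b ~ N(0, Sigma), a complete longitudinal
# vector over all M visits, discrete dropout and death times by sequential
# Bernoulli trials on the probit hazards, and an independent censoring time.
# The observed record is then assembled exactly as in the semicompeting
# observation scheme: D* = min(D, S, C), delta_D = 1[D <= C, D <= S],
# S* = min(S, C), delta_S = 1[S <= C]. Per-patient RNG substreams
# (L'Ecuyer-CMRG) make patient i's data invariant to the total sample size.

#' Simulation configuration
#'
#' @param N Number of patients.
#' @param scheme A [jm_scheme()].
#' @param design A [jm_design()].
#' @param params True [jm_params()].
#' @param covariate_generator Function taking a number of patients and
#'   returning a data frame of baseline covariates with that many rows; it
#'   is called once per patient under that patient's RNG substream.
#' @param censor_probs Distribution of the independent censoring time over
#'   visits `1..M`; defaults to administrative censoring at `M` (all mass on
#'   the final visit).
#' @param p_int Probability that a scheduled measurement before the
#'   truncation time is intermittently missing (never applied to visit 1).
#' @param int_mar Optional list `list(intercept, slope)`; if supplied,
#'   intermittent missingness is missing-at-random with probability
#'   `plogis(intercept + slope * y_prev)` depending on the previous observed
#'   outcome, instead of the constant `p_int`.
#' @param obs_at_death_interval If `FALSE` (default), no measurement is
#'   taken in the interval in which death terminates follow-up.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(N, scheme, design, params, covariate_generator,
                       censor_probs = NULL, p_int = 0.076, int_mar = NULL,
                       obs_at_death_interval = FALSE) {
  stopifnot(inherits(scheme, "jm_scheme"), inherits(design, "jm_design"),
            inherits(params, "jm_params"))
  check_params_design(params, design)
  if (p_int < 0 || p_int >= 1) stop("p_int must be in [0, 1)")
  if (is.null(censor_probs)) censor_probs <- c(rep(0, scheme$M - 1L), 1)
  if (length(censor_probs) != scheme$M || any(censor_probs < 0) ||
      abs(sum(censor_probs) - 1) > 1e-8)
    stop("censor_probs must be a probability vector over 1..M")
  structure(list(N = as.integer(N), scheme = scheme, design = design,
                 params = params, covariate_generator = covariate_generator,
                 censor_probs = censor_probs, p_int = p_int,
                 int_mar = int_mar,
                 obs_at_death_interval = isTRUE(obs_at_death_interval)),
            class = "sim_config")
}

# sequential Bernoulli draw of a discrete event time; M+1 means "never"
draw_event_time <- function(lp) {
  M <- length(lp)
  h <- probit_hazard(lp)
  u <- stats::runif(M)
  hit <- which(u < h)
  if (length(hit)) hit[1L] else M + 1L
}

#' Simulate one patient
#'
#' Draws a patient's latent quantities and assembles the observed record
#' under the semicompeting observation scheme. Uses the RNG state of the
#' caller; [simulate_dataset()] supplies per-patient substreams.
#'
#' @param config A [sim_config()].
#' @param covars One-row data frame of the patient's baseline covariates.
#' @param id Patient id.
#' @return List with `long` (observed rows), `events` (one-row data frame)
#'   and `truth` (random effects, latent event/censoring times, complete
#'   outcome vector).
#' @export
simulate_patient <- function(config, covars, id = 1L) {
  des <- config$design; prm <- config$params; M <- config$scheme$M
  q <- des$q
  b <- drop(crossprod(chol(prm$Sigma), stats::rnorm(q)))
  X <- design_matrix(des$fixed, covars, seq_len(M), M)
  Z <- design_matrix(des$random, covars, seq_len(M), M)
  y_complete <- drop(X %*% prm$beta) + drop(Z %*% b) +
    stats::rnorm(M, sd = sqrt(prm$sigma2_eps))

  lp_event <- function(terms, alpha, gamma, W) {
    Xh <- design_matrix(terms, covars, seq_len(M), M)
    lp <- drop(Xh %*% alpha)
    for (j in seq_len(M))
      lp[j] <- lp[j] + sum((W %*% b) * gamma_at(gamma, j))
    lp
  }
  D <- draw_event_time(lp_event(des$dropout, prm$alpha_D, prm$gamma_D, des$W_D))
  S <- draw_event_time(lp_event(des$death, prm$alpha_S, prm$gamma_S, des$W_S))
  C <- sample.int(M, 1L, prob = config$censor_probs)

  D_star <- min(D, S, C)
  delta_D <- as.integer(D <= C && D <= S)
  S_star <- min(S, C)
  delta_S <- as.integer(S <= C)

  visits <- seq_len(D_star)
  death_terminates <- delta_S == 1L && S == D_star && delta_D == 0L
  if (death_terminates && !config$obs_at_death_interval)
    visits <- setdiff(visits, D_star)

  # intermittent missingness: visit 1 (enrolment) is always kept
  if (length(visits)) {
    keep <- rep(TRUE, length(visits))
    if (is.null(config$int_mar)) {
      if (config$p_int > 0) {
        u <- stats::runif(length(visits))
        keep <- u >= config$p_int | visits == 1L
      }
    } else {
      u <- stats::runif(length(visits))
      prev <- y_complete[1L]
      for (k in seq_along(visits)) {
        if (visits[k] == 1L) { keep[k] <- TRUE }
        else {
          pmiss <- stats::plogis(config$int_mar$intercept +
                                   config$int_mar$slope * prev)
          keep[k] <- u[k] >= pmiss
        }
        if (keep[k]) prev <- y_complete[visits[k]]
      }
    }
    visits <- visits[keep]
  }

  long <- data.frame(id = rep(id, length(visits)), visit = visits,
                     y = y_complete[visits])
  events <- cbind(data.frame(id = id, D_star = D_star, delta_D = delta_D,
                             S_star = S_star, delta_S = delta_S),
                  covars, row.names = NULL)
  truth <- c(list(id = id, b = b, D = D, S = S, C = C,
                  y_complete = y_complete))
  list(long = long, events = events, truth = truth)
}

#' Simulate a full dataset
#'
#' `N` independent patients, each on its own L'Ecuyer-CMRG RNG substream
#' derived from `seed`, so the same seed reproduces the dataset exactly and
#' increasing `N` leaves earlier patients unchanged. The caller's RNG state
#' is preserved.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @return A [jm_data()] with attribute `truth`: a list with the generating
#'   `params`, `seed`, per-patient latents (`latents` data frame) and the
#'   complete outcome matrix `y_complete` (`N x M`).
#' @export
simulate_dataset <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  old_kind <- RNGkind()
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (had) assign(".Random.seed", old_seed, envir = globalenv())
  })
  RNGkind("L'Ecuyer-CMRG")
  set.seed(seed)
  stream <- get(".Random.seed", envir = globalenv())

  q <- config$design$q
  M <- config$scheme$M
  longs <- vector("list", config$N)
  evs <- vector("list", config$N)
  lat <- vector("list", config$N)
  ycomp <- matrix(NA_real_, config$N, M)
  for (i in seq_len(config$N)) {
    stream <- parallel::nextRNGStream(stream)
    assign(".Random.seed", stream, envir = globalenv())
    covars <- config$covariate_generator(1L)
    rec <- simulate_patient(config, covars, id = i)
    longs[[i]] <- rec$long
    evs[[i]] <- rec$events
    ycomp[i, ] <- rec$truth$y_complete
    lat[[i]] <- data.frame(id = i,
                           t(stats::setNames(rec$truth$b,
                                             paste0("b", seq_len(q)))),
                           D = rec$truth$D, S = rec$truth$S, C = rec$truth$C)
  }
  data <- jm_data(do.call(rbind, longs), do.call(rbind, evs),
                  config$scheme, config$design)
  attr(data, "truth") <- list(params = config$params, seed = seed,
                              latents = do.call(rbind, lat),
                              y_complete = ycomp)
  data
}

# baseline covariates emulating the HERS cohort: a 4-level baseline viral
# load factor (dummy-coded against the highest group), an HIV symptom count
# on 0..5 and a baseline antiretroviral therapy indicator
hers_covariate_generator <- function(n) {
  grp <- sample.int(4L, n, replace = TRUE, prob = c(0.25, 0.30, 0.25, 0.20))
  data.frame(vl_low = as.numeric(grp == 1L),
             vl_med = as.numeric(grp == 2L),
             vl_high = as.numeric(grp == 3L),
             symptoms = stats::rbinom(n, 5L, 0.2),
             therapy = stats::rbinom(n, 1L, 0.35))
}

#' HERS-like simulation configuration
#'
#' The default study conditions emulated by the simulator: 12 scheduled
#' visits, a square-root CD4-like Gaussian outcome with random intercept and
#' slope, probit hazards of dropout and death driven by baseline viral load
#' group, symptom count, therapy, quadratic visit effects (`j/M`,
#' `(j/M)^2`) and the shared random effects, administrative censoring at the
#' final visit, and 7.6% intermittent missingness. True parameter values are
#' the fitted values reported for the HERS cohort.
#'
#' @param N Number of patients (default 827).
#' @param M Number of visits (default 12); the hazard time effects are on
#'   the `j/M` scale so the same coefficients define a scaled-down design.
#' @return A [sim_config()].
#' @export
hers_like_config <- function(N = 827L, M = 12L) {
  scheme <- if (M == 12L) hers_scheme() else
    jm_scheme(seq(0, by = 182, length.out = M + 1L))
  base <- c("vl_low", "vl_med", "vl_high", "symptoms", "therapy")
  design <- jm_design(
    fixed = c("1", "visit", base, paste0(base, ":visit")),
    random = c("1", "visit"),
    dropout = c("1", "visit_frac", "visit_frac_sq", base),
    death = c("1", "visit_frac", "visit_frac_sq", base))
  params <- jm_params(
    beta = c(15.080, -0.863, 10.040, 6.623, 2.977, -0.115, -4.653,
             0.464, 0.433, 0.273, -0.049, 0.109),
    alpha_D = c(1.052, 1.190, -1.733, 0.733, 0.650, 0.269, -0.011, -0.043),
    gamma_D = c(0.029, 0.443),
    alpha_S = c(3.472, -4.272, 2.931, 2.032, 1.194, 0.539, -0.121, -0.516),
    gamma_S = c(0.128, 1.192),
    sigma2_eps = 7.304,
    cov = cov_from_moments(29.120, 0.539, -0.305))
  sim_config(N = N, scheme = scheme, design = design, params = params,
             covariate_generator = hers_covariate_generator)
}

#' Covariance from variances and a correlation (q = 2)
#'
#' @param var1,var2 Variances of the random intercept and slope.
#' @param corr Their correlation.
#' @return A [cholesky_cov()].
#' @export
cov_from_moments <- function(var1, var2, corr) {
  cov12 <- corr * sqrt(var1 * var2)
  recover_cholesky(matrix(c(var1, cov12, cov12, var2), 2))
}
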