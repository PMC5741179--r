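# Readers and writers: CSV data, YAML/JSON model configuration, JSON
# parameter files, CSV posterior draws.

#' Read a model configuration
#'
#' A configuration file (YAML or JSON) declares the visit scheme and the
#' design term lists, e.g.
#' ```yaml
#' scheme:
#'   cutpoints: [0, 91, 273, ...]      # or  M: 12  with equal intervals
#' design:
#'   fixed: ["1", "visit", "therapy", "therapy:visit"]
#'   random: ["1", "visit"]
#'   dropout: ["1", "visit_frac", "visit_frac_sq", "therapy"]
#'   death: ["1", "visit_frac", "visit_frac_sq", "therapy"]
#'   gamma_by_visit: false
#' ```
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or an equivalent
#'   list.
#' @return List with elements `scheme` ([jm_scheme()]) and `design`
#'   ([jm_design()]).
#' @export
read_jm_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config) || is.null(config$design))
    stop("config must contain a 'design' block")
  sc <- config$scheme
  scheme <- if (!is.null(sc$cutpoints)) jm_scheme(as.numeric(sc$cutpoints))
  else if (!is.null(sc$M))
    jm_scheme(seq(0, by = 182, length.out = as.integer(sc$M) + 1L))
  else stop("config scheme must give 'cutpoints' or 'M'")
  d <- config$design
  design <- jm_design(fixed = unlist(d$fixed), random = unlist(d$random),
                      dropout = unlist(d$dropout), death = unlist(d$death),
                      W_D = if (!is.null(d$W_D)) do.call(rbind, d$W_D),
                      W_S = if (!is.null(d$W_S)) do.call(rbind, d$W_S),
                      gamma_by_visit = isTRUE(d$gamma_by_visit))
  list(scheme = scheme, design = design)
}

#' Read a joint-model dataset from CSV files
#'
#' @param long_csv Path to the long-format longitudinal CSV (`id`, `visit`,
#'   `y`).
#' @param events_csv Path to the one-row-per-patient events CSV (`id`,
#'   `D_star`, `delta_D`, `S_star`, `delta_S`, baseline covariates).
#' @param config Configuration (path or list), see [read_jm_config()].
#' @return A validated [jm_data()].
#' @export
read_jm_data <- function(long_csv, events_csv, config) {
  for (f in c(long_csv, events_csv))
    if (!file.exists(f)) stop("file not found: ", f)
  cfg <- read_jm_config(config)
  long <- utils::read.csv(long_csv)
  events <- utils::read.csv(events_csv)
  jm_data(long, events, cfg$scheme, cfg$design)
}

#' Write a joint-model dataset to CSV files
#'
#' Writes `long.csv` and `events.csv` into `dir`; when the dataset carries a
#' simulation truth attribute, also `truth.json` (generating parameters and
#' seed) and `truth_latents.csv` (per-patient random effects and latent
#' event times).
#'
#' @param data A [jm_data()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_jm_data <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data$long, file.path(dir, "long.csv"), row.names = FALSE)
  utils::write.csv(data$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  tr <- attr(data, "truth")
  if (!is.null(tr)) {
    jsonlite::write_json(c(params_to_list(tr$params), list(seed = tr$seed)),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(tr$latents, file.path(dir, "truth_latents.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

params_to_list <- function(params) {
  list(beta = params$beta, alpha_D = params$alpha_D,
       gamma_D = params$gamma_D, alpha_S = params$alpha_S,
       gamma_S = params$gamma_S, sigma2_eps = params$sigma2_eps,
       lambda = params$cov$lambda,
       innovation_vars = params$cov$innovation_vars)
}

#' Read or write joint-model parameters as JSON
#'
#' @param path File path.
#' @return `params_from_json` returns a [jm_params()].
#' @export
params_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  jm_params(beta = x$beta, alpha_D = x$alpha_D, gamma_D = x$gamma_D,
            alpha_S = x$alpha_S, gamma_S = x$gamma_S,
            sigma2_eps = x$sigma2_eps,
            cov = cholesky_cov(if (is.null(x$lambda)) numeric(0) else
              x$lambda, x$innovation_vars))
}

#' @rdname params_from_json
#' @param params A [jm_params()].
#' @export
params_to_json <- function(params, path) {
  jsonlite::write_json(params_to_list(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# posterior draws round-trip through CSV, keyed to a design
write_draws_csv <- function(draws, path) {
  df <- data.frame(chain = draws$chain, draws$draws, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_draws_csv <- function(path, design) {
  df <- utils::read.csv(path, check.names = FALSE)
  structure(list(draws = as.matrix(df[, -1L, drop = FALSE]),
                 chain = df[[1L]], design = design, prior = NULL,
                 engine = "file", warmup = NA, seed = NA, b_mean = NULL),
            class = "jm_draws")
}
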