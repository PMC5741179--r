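#' Declarative covariate designs for the three submodels
#'
#' A design declares, as character vectors of terms, which columns enter the
#' fixed-effects part of the longitudinal model (`fixed`), the random-effects
#' part (`random`), and the linear predictors of the dropout and death
#' hazards (`dropout`, `death`). Terms are resolved against the per-patient
#' covariate table (one row per patient, baseline covariates) plus the
#' pseudo-columns
#' \describe{
#'   \item{`"1"`}{intercept,}
#'   \item{`"visit"`}{the visit number `j`,}
#'   \item{`"visit_sq"`}{`j^2`,}
#'   \item{`"visit_frac"`}{`j / M`,}
#'   \item{`"visit_frac_sq"`}{`(j / M)^2`.}
#' }
#' Products are written with `:`, e.g. `"therapy:visit"` for a baseline-by-
#' time interaction.
#'
#' `W_D` and `W_S` map the `q` shared random effects into the hazard linear
#' predictors (coefficients `gamma`); they default to the `q x q` identity,
#' i.e. the hazards load on the random intercept and slope directly.
#'
#' @param fixed Character vector of terms for \eqn{x_{ij}} (length `p`).
#' @param random Character vector of terms for \eqn{z_{ij}} (length `q`);
#'   default random intercept and slope.
#' @param dropout,death Character vectors of terms for the hazard covariates
#'   \eqn{x_{D,ij}} and \eqn{x_{S,ij}}.
#' @param W_D,W_S Optional fixed matrices (`q_D x q`, `q_S x q`) applied to
#'   the random effects inside the hazards; identity by default.
#' @param gamma_by_visit Logical; if `TRUE` the association parameters
#'   `gamma` are allowed to differ by visit (one row per visit). The default
#'   `FALSE` uses a single `gamma` for all visits.
#' @return An object of class `jm_design`.
#' @export
jm_design <- function(fixed, random = c("1", "visit"), dropout, death,
                      W_D = NULL, W_S = NULL, gamma_by_visit = FALSE) {
  q <- length(random)
  if (length(fixed) < 1L || q < 1L) stop("fixed and random terms required")
  if (is.null(W_D)) W_D <- diag(q)
  if (is.null(W_S)) W_S <- diag(q)
  W_D <- as.matrix(W_D); W_S <- as.matrix(W_S)
  if (ncol(W_D) != q || ncol(W_S) != q)
    stop("W matrices must have q = ", q, " columns")
  structure(
    list(fixed = fixed, random = random, dropout = dropout, death = death,
         p = length(fixed), q = q,
         p_D = length(dropout), p_S = length(death),
         q_D = nrow(W_D), q_S = nrow(W_S),
         W_D = W_D, W_S = W_S,
         gamma_by_visit = isTRUE(gamma_by_visit)),
    class = "jm_design")
}

#' @export
print.jm_design <- function(x, ...) {
  cat("Joint model design\n")
  cat("  fixed   (p =", x$p, "):", paste(x$fixed, collapse = ", "), "\n")
  cat("  random  (q =", x$q, "):", paste(x$random, collapse = ", "), "\n")
  cat("  dropout (p_D =", x$p_D, "):", paste(x$dropout, collapse = ", "), "\n")
  cat("  death   (p_S =", x$p_S, "):", paste(x$death, collapse = ", "), "\n")
  if (x$gamma_by_visit) cat("  gamma varies by visit\n")
  invisible(x)
}

# resolve one atomic term for parallel vectors of covariate rows and visits
resolve_atom <- function(atom, covars, visit, M) {
  n <- length(visit)
  switch(atom,
    "1" = rep(1, n),
    "visit" = as.numeric(visit),
    "visit_sq" = as.numeric(visit)^2,
    "visit_frac" = as.numeric(visit) / M,
    "visit_frac_sq" = (as.numeric(visit) / M)^2,
    {
      if (!atom %in% names(covars))
        stop("unknown design term '", atom, "': not a pseudo-column or a ",
             "covariate column")
      v <- covars[[atom]]
      if (!is.numeric(v)) stop("covariate column '", atom, "' must be numeric")
      as.numeric(v)
    })
}

#' Build a design matrix from declarative terms
#'
#' @param terms Character vector of terms (see [jm_design()]).
#' @param covars Data frame of covariate values, one row per requested row.
#' @param visit Integer vector of visit numbers, recycled against `covars`.
#' @param M Number of scheduled visits (scales the `visit_frac` terms).
#' @return Numeric matrix with one column per term.
#' @keywords internal
#' @export
design_matrix <- function(terms, covars, visit, M) {
  nv <- length(visit); nc <- nrow(covars)
  if (nc == 1L && nv != 1L) {
    covars <- covars[rep(1L, nv), , drop = FALSE]
  } else if (nv == 1L && nc != 1L) {
    visit <- rep(visit, nc)
  } else if (nv != nc) {
    stop("covars (", nc, " rows) and visit (length ", nv,
         ") are not conformable")
  }
  n <- length(visit)
  out <- matrix(NA_real_, n, length(terms),
                dimnames = list(NULL, terms))
  for (s in seq_along(terms)) {
    atoms <- strsplit(terms[s], ":", fixed = TRUE)[[1L]]
    col <- rep(1, n)
    for (a in atoms) col <- col * resolve_atom(a, covars, visit, M)
    out[, s] <- col
  }
  out
}

# gamma row for visit j (matrix params have one row per visit)
gamma_at <- function(gamma, j) {
  if (is.matrix(gamma)) gamma[j, ] else gamma
}
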