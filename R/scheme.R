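#' Discrete visit scheme for the joint model
#'
#' Defines the partition of the continuous follow-up period `[0, T_total]`
#' into `M` half-open intervals, each containing one scheduled visit of the
#' longitudinal outcome. Dropout and death times live on the induced discrete
#' timescale `1, ..., M`.
#'
#' @param cutpoints Numeric vector of `M + 1` strictly increasing interval
#'   boundaries starting at 0; the last element is the total scheduled
#'   follow-up time.
#' @return An object of class `jm_scheme` with elements `M`, `cutpoints` and
#'   `T_total`.
#' @examples
#' sch <- jm_scheme(c(0, 91, seq(91 + 182, 2093, by = 182)))
#' sch$M
#' @seealso [discretize_time()], [hers_scheme()]
#' @export
jm_scheme <- function(cutpoints) {
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) < 2L)
    stop("need at least 2 cutpoints (one interval)")
  if (cutpoints[1L] != 0)
    stop("first cutpoint must be 0")
  if (any(diff(cutpoints) <= 0))
    stop("cutpoints must be strictly increasing")
  structure(
    list(M = length(cutpoints) - 1L,
         cutpoints = cutpoints,
         T_total = cutpoints[length(cutpoints)]),
    class = "jm_scheme")
}

#' The HERS visit scheme
#'
#' Twelve intervals over 2093 days of follow-up: a first interval of 3 months
#' from enrolment, then eleven 6-month intervals, each containing one
#' scheduled CD4 measurement.
#'
#' @return A [jm_scheme()] with `M = 12`.
#' @export
hers_scheme <- function() {
  jm_scheme(c(0, 91, 91 + 182 * seq_len(11)))
}

#' @export
print.jm_scheme <- function(x, ...) {
  cat("Visit scheme: M =", x$M, "intervals on [0,", x$T_total, "]\n")
  cat("cutpoints:", paste(x$cutpoints, collapse = ", "), "\n")
  invisible(x)
}

#' Map a continuous time to its visit interval
#'
#' Intervals are half-open `[left, right)`; the last interval is closed on
#' the right so that the map is a surjection from `[0, T_total]` onto
#' `1, ..., M`. A time falling exactly on an interior cutpoint belongs to the
#' later interval.
#'
#' @param t Numeric vector of times in `[0, T_total]`.
#' @param scheme A [jm_scheme()].
#' @return Integer vector of visit indices in `1, ..., M`.
#' @examples
#' discretize_time(c(0, 91, 2093), hers_scheme())
#' @export
discretize_time <- function(t, scheme) {
  stopifnot(inherits(scheme, "jm_scheme"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0) || any(t > scheme$T_total))
    stop("times must lie in [0, ", scheme$T_total, "]")
  j <- findInterval(t, scheme$cutpoints, rightmost.closed = TRUE)
  as.integer(pmin(j, scheme$M))
}
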