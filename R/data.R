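#' Assemble a joint-model dataset
#'
#' Combines long-format longitudinal rows with one-record-per-patient
#' semicompeting event data and validates the structural constraints of the
#' observed-data layout: the observed dropout time `D_star` never exceeds the
#' observed death time `S_star`, observed visits never exceed `D_star`, and
#' the two event indicators are 0/1. Longitudinal rows with a missing
#' outcome are dropped and become intermittent gaps.
#'
#' @param long Data frame with columns `id`, `visit`, `y`. Visits are the
#'   1-based scheduled visit numbers.
#' @param events Data frame with columns `id`, `D_star`, `delta_D`,
#'   `S_star`, `delta_S` plus any baseline covariate columns used by the
#'   design.
#' @param scheme A [jm_scheme()].
#' @param design A [jm_design()].
#' @return Object of class `jm_data` with elements `long`, `events`,
#'   `scheme`, `design`, `N`.
#' @export
jm_data <- function(long, events, scheme, design) {
  stopifnot(inherits(scheme, "jm_scheme"), inherits(design, "jm_design"))
  long <- as.data.frame(long)
  events <- as.data.frame(events)
  need_l <- c("id", "visit", "y")
  need_e <- c("id", "D_star", "delta_D", "S_star", "delta_S")
  if (!all(need_l %in% names(long)))
    stop("long data needs columns: ", paste(need_l, collapse = ", "))
  if (!all(need_e %in% names(events)))
    stop("events data needs columns: ", paste(need_e, collapse = ", "))
  if (anyDuplicated(events$id))
    stop("duplicated patient ids in events: ",
         paste(unique(events$id[duplicated(events$id)]), collapse = ", "))

  drop_na <- is.na(long$y)
  if (any(drop_na)) {
    message(sum(drop_na), " longitudinal rows with missing outcome dropped ",
            "(treated as intermittent gaps)")
    long <- long[!drop_na, , drop = FALSE]
  }

  bad <- function(rows, what)
    stop("invalid ", what, " at events row(s) ",
         paste(utils::head(rows, 5L), collapse = ", "),
         if (length(rows) > 5L) " ...", call. = FALSE)
  M <- scheme$M
  ev <- events
  if (!all(ev$delta_D %in% c(0, 1)))
    bad(which(!ev$delta_D %in% c(0, 1)), "dropout indicator (must be 0/1)")
  if (!all(ev$delta_S %in% c(0, 1)))
    bad(which(!ev$delta_S %in% c(0, 1)), "death indicator (must be 0/1)")
  if (any(ev$D_star %% 1 != 0) || any(ev$D_star < 1) || any(ev$D_star > M))
    bad(which(ev$D_star %% 1 != 0 | ev$D_star < 1 | ev$D_star > M),
        paste0("D_star (must be integer in 1..", M, ")"))
  if (any(ev$S_star %% 1 != 0) || any(ev$S_star < 1) || any(ev$S_star > M))
    bad(which(ev$S_star %% 1 != 0 | ev$S_star < 1 | ev$S_star > M),
        paste0("S_star (must be integer in 1..", M, ")"))
  if (any(ev$D_star > ev$S_star))
    bad(which(ev$D_star > ev$S_star), "ordering (D_star > S_star)")

  if (!all(long$id %in% ev$id))
    stop("longitudinal rows for unknown patient id(s): ",
         paste(utils::head(setdiff(long$id, ev$id), 5L), collapse = ", "))
  if (any(long$visit %% 1 != 0) || any(long$visit < 1) || any(long$visit > M))
    stop("longitudinal visit outside 1..", M, " at long row(s) ",
         paste(utils::head(
           which(long$visit %% 1 != 0 | long$visit < 1 | long$visit > M), 5L),
           collapse = ", "))
  dstar <- ev$D_star[match(long$id, ev$id)]
  if (any(long$visit > dstar))
    stop("observed visit after D_star at long row(s) ",
         paste(utils::head(which(long$visit > dstar), 5L), collapse = ", "))
  key <- paste(long$id, long$visit)
  if (anyDuplicated(key))
    stop("duplicated (id, visit) at long row(s) ",
         paste(utils::head(which(duplicated(key)), 5L), collapse = ", "))

  miss <- setdiff(c(design$fixed, design$dropout, design$death), "")
  atoms <- unique(unlist(strsplit(c(miss, design$random), ":", fixed = TRUE)))
  pseudo <- c("1", "visit", "visit_sq", "visit_frac", "visit_frac_sq")
  cols <- setdiff(atoms, pseudo)
  if (!all(cols %in% names(ev)))
    stop("design refers to missing covariate column(s): ",
         paste(setdiff(cols, names(ev)), collapse = ", "))

  long <- long[order(match(long$id, ev$id), long$visit), , drop = FALSE]
  rownames(long) <- NULL
  structure(list(long = long, events = ev, scheme = scheme, design = design,
                 N = nrow(ev)),
            class = "jm_data")
}

#' @export
print.jm_data <- function(x, ...) {
  cat("Joint-model dataset: N =", x$N, "patients,",
      nrow(x$long), "longitudinal observations, M =", x$scheme$M, "\n")
  tab <- table(factor(x$events$delta_D, levels = 0:1),
               factor(x$events$delta_S, levels = 0:1),
               dnn = c("delta_D", "delta_S"))
  print(tab)
  invisible(x)
}

#' Extract one patient's record with design matrices
#'
#' Returns the patient's observed longitudinal rows and event data together
#' with the design matrices evaluated at the relevant visits: `X`, `Z` at
#' the observed visits, and the hazard covariate matrices `XD`, `XS` at
#' visits `1..D_star` and `1..S_star`.
#'
#' @param data A [jm_data()].
#' @param id A patient id present in `data$events$id`.
#' @return A list of class `jm_patient`.
#' @export
jm_patient <- function(data, id) {
  i <- match(id, data$events$id)
  if (is.na(i)) stop("unknown patient id: ", id)
  build_patient(data, i)
}

build_patient <- function(data, i) {
  des <- data$design
  M <- data$scheme$M
  ev <- data$events[i, , drop = FALSE]
  rows <- data$long[data$long$id == ev$id, , drop = FALSE]
  visits <- as.integer(rows$visit)
  structure(list(
    id = ev$id,
    visits = visits,
    y = as.numeric(rows$y),
    n = length(visits),
    D_star = as.integer(ev$D_star), delta_D = as.integer(ev$delta_D),
    S_star = as.integer(ev$S_star), delta_S = as.integer(ev$delta_S),
    X = design_matrix(des$fixed, ev, visits, M),
    Z = design_matrix(des$random, ev, visits, M),
    XD = design_matrix(des$dropout, ev, seq_len(ev$D_star), M),
    XS = design_matrix(des$death, ev, seq_len(ev$S_star), M),
    covars = ev, design = des), class = "jm_patient")
}

# list of all patients' records (used by likelihood / samplers)
patient_list <- function(data) {
  lapply(seq_len(data$N), function(i) build_patient(data, i))
}

#' Validate a joint-model dataset
#'
#' Re-runs all structural checks of [jm_data()] on an existing object.
#'
#' @param data A [jm_data()].
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_dataset <- function(data) {
  stopifnot(inherits(data, "jm_data"))
  jm_data(data$long, data$events, data$scheme, data$design)
  invisible(TRUE)
}
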