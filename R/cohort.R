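#' Validate a cohort data frame
#'
#' A cohort is an ordinary data frame with one row per phase-I subject and at
#' least the columns `time` (follow-up time `X = min(T, C)`, nonnegative) and
#' `cause` (integer event code: 0 = censored, `k` in `1..K` = failure from
#' cause `k`). Optional columns: `id` (subject label), `stratum` (used by
#' stratified designs) and any covariates (e.g. a `group` column for
#' subgroup estimation). Subjects not selected into phase II may carry a
#' missing `cause` when the outcome itself is a phase-II variable; `cause`
#' must then be observed wherever the selection indicator is 1.
#'
#' @param data A data frame with columns `time` and `cause`.
#' @param selection Optional [two_phase_design] used to decide which rows
#'   must have an observed outcome.
#' @return The validated data invisibly (as a tibble), or an error naming the
#'   offending rows.
#' @export
validate_cohort <- function(data, selection = NULL) {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  need <- setdiff(c("time", "cause"), names(data))
  if (length(need)) {
    stop("cohort is missing column(s): ", paste(need, collapse = ", "), call. = FALSE)
  }
  time <- data$time
  cause <- data$cause
  if (!is.null(selection) && length(selection$xi) != nrow(data)) {
    stop("selection is not aligned to the cohort: ", length(selection$xi),
      " indicators for ", nrow(data), " rows",
      call. = FALSE
    )
  }
  sel <- if (is.null(selection)) rep(TRUE, nrow(data)) else selection$xi == 1L
  bad_t <- which(is.na(time) | time < 0)
  if (length(bad_t)) {
    stop("negative or missing `time` at row(s) ", row_list(bad_t), call. = FALSE)
  }
  bad_c <- which((is.na(cause) & sel) |
    (!is.na(cause) & (cause < 0 | cause != floor(cause))))
  if (length(bad_c)) {
    stop("invalid or missing `cause` code at row(s) ", row_list(bad_c), call. = FALSE)
  }
  invisible(as_tibble(data))
}

row_list <- function(i) paste(utils::head(i, 5), collapse = ", ")

#' Number of failure causes in a cohort
#'
#' @param data A cohort data frame (see [validate_cohort()]).
#' @return Sorted vector of positive cause codes present.
#' @export
cohort_causes <- function(data) {
  sort(unique(data$cause[!is.na(data$cause) & data$cause > 0]))
}

# Extract the selected subjects of a cohort as plain sorted vectors.
# Returns x (time), d (cause), w (1/pi), pi, and the order mapping back to
# the rows of `data`. `rows` optionally restricts to a subset of cohort rows
# (subgroup estimation). All downstream estimation works off this.
tp_prepare <- function(data, selection, rows = NULL) {
  validate_cohort(data, selection)
  if (length(selection$xi) != nrow(data)) {
    stop("selection is not aligned to the cohort: ", length(selection$xi),
      " indicators for ", nrow(data), " rows",
      call. = FALSE
    )
  }
  sel <- which(selection$xi == 1L)
  if (!is.null(rows)) sel <- intersect(sel, rows)
  if (!length(sel)) stop("empty phase-II selection: no subject has xi = 1", call. = FALSE)
  pi <- selection$pi[sel]
  if (any(is.na(pi) | pi <= 0 | pi > 1)) {
    stop("invalid design: pi must be in (0, 1] for every selected subject", call. = FALSE)
  }
  ord <- sel[order(data$time[sel])]
  list(
    idx = ord, # row indices into `data`, sorted by time
    x = data$time[ord],
    d = as.integer(data$cause[ord]),
    pi = selection$pi[ord],
    w = 1 / selection$pi[ord]
  )
}

#' Design-weighted counting processes
#'
#' Computes the Horvitz-Thompson estimates of the cohort-level counting
#' processes from the phase-II sample: the weighted count of cause-`k`
#' events \eqn{\hat N_{\cdot k}(t) = \sum_i \xi_i N_{ik}(t)/\pi_i}, the
#' weighted number at risk \eqn{\hat Y_\cdot(t) = \sum_i \xi_i Y_i(t)/\pi_i}
#' with \eqn{Y_i(t) = I(X_i \ge t)}, and the weighted count of censorings
#' \eqn{\hat N^c_\cdot(t)}. \eqn{\hat Y_\cdot(0)} estimates the phase-I size
#' `N`.
#'
#' @param data A cohort data frame (see [validate_cohort()]).
#' @param selection A [two_phase_design].
#' @param cause Positive integer cause code.
#' @return A list with components `N_k`, `Y`, `N_c`, each a [step_function()].
#'   `Y` uses the left-continuous at-risk convention (evaluation at `t`
#'   counts subjects with `X >= t`).
#' @examples
#' d <- data.frame(time = 1:4, cause = c(1, 2, 0, 1))
#' cp <- counting_processes(d, design_full(d), cause = 1)
#' step_eval(cp$N_k, 4) # 2 cause-1 events by t = 4
#' step_eval(cp$Y, 4) # 1 subject still at risk at t = 4
#' @export
counting_processes <- function(data, selection, cause) {
  stopifnot(length(cause) == 1L, cause >= 1)
  prep <- tp_prepare(data, selection)
  tu <- unique(prep$x)
  wsum <- function(keep) {
    agg <- rowsum(prep$w * keep, group = prep$x, reorder = TRUE)
    cumsum(agg[, 1])
  }
  Nk <- wsum(prep$d == cause)
  Nc <- wsum(prep$d == 0L)
  Y0 <- sum(prep$w)
  Yafter <- Y0 - wsum(rep(TRUE, length(prep$x))) # sum w over X > t
  list(
    N_k = step_function(tu, Nk, v0 = 0, side = "right"),
    Y = step_function(tu, Yafter, v0 = Y0, side = "left"),
    N_c = step_function(tu, Nc, v0 = 0, side = "right")
  )
}
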