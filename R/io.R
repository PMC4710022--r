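#' Read a cohort (and optional selection) from a delimited file
#'
#' Expects a header row and at least the columns `time` and `cause` (or
#' `status`); optional columns: `id`, `stratum`, `group`, and the phase-II
#' fields `selected` (0/1) and `pi` (first-order inclusion probability).
#' When `selected`/`pi` are present a custom [two_phase_design] is built,
#' with pairwise probabilities defaulting to \eqn{\pi_i\pi_j}. Rows with
#' `selected = 1` must carry a valid `pi` in (0, 1] and an observed cause;
#' unselected rows may have a missing cause (outcome ascertained only at
#' phase II). Validation failures report the offending data row.
#'
#' @param path Path to a delimited text file (separator inferred by
#'   [readr::read_delim()]; comma by default).
#' @param column_map Optional named character vector renaming file columns
#'   to the standard names, e.g. `c(time = "fup_years", cause = "ev_type")`.
#' @return A list with elements `cohort` (tibble) and `selection` (a
#'   `two_phase_design`, or `NULL` when the file has no phase-II columns).
#' @export
read_cohort <- function(path, column_map = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(raw)) {
        stop("column '", src, "' (mapped to '", std, "') not found in ", path,
          call. = FALSE
        )
      }
      names(raw)[names(raw) == src] <- std
    }
  }
  if (!"cause" %in% names(raw) && "status" %in% names(raw)) {
    names(raw)[names(raw) == "status"] <- "cause"
  }
  need <- setdiff(c("time", "cause"), names(raw))
  if (length(need)) {
    stop("input file is missing column(s): ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  selection <- NULL
  if ("selected" %in% names(raw) || "pi" %in% names(raw)) {
    if (!all(c("selected", "pi") %in% names(raw))) {
      stop("phase-II input needs both `selected` and `pi` columns", call. = FALSE)
    }
    xi <- as.integer(raw$selected)
    if (anyNA(xi) || !all(xi %in% 0:1)) {
      stop("`selected` must be 0/1 at row(s) ",
        row_list(which(is.na(xi) | !xi %in% 0:1)),
        call. = FALSE
      )
    }
    bad_pi <- which(xi == 1L & (is.na(raw$pi) | raw$pi <= 0 | raw$pi > 1))
    if (length(bad_pi)) {
      stop("`pi` must be in (0, 1] for selected row(s) ", row_list(bad_pi),
        call. = FALSE
      )
    }
    selection <- design_custom(raw, xi = xi, pi = raw$pi)
  }
  cohort <- validate_cohort(raw, selection)
  list(cohort = cohort, selection = selection)
}

#' Read a simulation scenario from a YAML configuration file
#'
#' Recognised keys mirror the [sim_scenario()] arguments (`design_kind`,
#' `m`, `total_hazard`, `cause_split`, `censor_low`, `censor_high`,
#' `admin_horizon`, `B`, `eval_times`, `alpha`, `seed`, an optional
#' `covariate` block with `p1`, `hazard0`, `hazard1`) with two spelling
#' notes: because a bare `n`/`N` is a YAML boolean, the phase-II size is
#' written `n_phase2` and the cohort size `n_cohort` (quoted `"n"`/`"N"`
#' also work). Unrecognised keys raise an error.
#'
#' @param path Path to a YAML file.
#' @return A `sim_scenario`.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  alias <- c(n_phase2 = "n", n_cohort = "N")
  for (a in names(alias)) {
    if (a %in% names(cfg)) names(cfg)[names(cfg) == a] <- alias[[a]]
  }
  allowed <- names(formals(sim_scenario))
  extra <- setdiff(names(cfg), allowed)
  if (length(extra)) {
    stop("unknown scenario key(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  do.call(sim_scenario, cfg)
}

#' Write an estimate table to a delimited file
#'
#' @param fit A `twophase_cif` from [cif_twophase()].
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_estimates <- function(fit, path) {
  stopifnot(inherits(fit, "twophase_cif"))
  readr::write_csv(fit$estimates, path)
  invisible(path)
}
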