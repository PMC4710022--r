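#' Simulation scenario for the two-phase crude-incidence estimator
#'
#' Configures the cohort generator and phase-II design for the operating
#' characteristics study. The default scenario is two competing causes whose
#' crude incidences are \eqn{F_1(t) = F_2(t) = \tfrac12(1 - e^{-0.1t})}
#' (all-cause exponential hazard 0.1 split equally between causes — about a
#' 9\% cause-1 incidence and 82\% event-free by `t = 2`), uniform random
#' censoring on (0.5, 10.5) (about 15\% censored before `t = 2`),
#' administrative censoring at `t = 2`, phase-I size `N = 1000`, and one of
#' four phase-II designs. The stratified scenario adds a binary covariate
#' `z` (frequency 30\% for `z = 1`) with all-cause hazards 0.08 (`z = 0`)
#' and 0.2 (`z = 1`); its true cause-1 incidence is the corresponding
#' mixture. Cause-1 cases are defined as observed cause-1 events by the
#' administrative horizon.
#'
#' @param design_kind One of `"random"`, `"case_control"`, `"stratified"`,
#'   `"ncc"`, or `"full"` (census benchmark).
#' @param n Phase-II size for random / case-control (total) / stratified
#'   (split equally over the 4 strata `z` x case).
#' @param m Controls per case for the nested case-control design.
#' @param N Phase-I cohort size.
#' @param total_hazard All-cause event hazard (per time unit).
#' @param cause_split Probability that an event is of cause 1.
#' @param censor_low,censor_high Support of the uniform random censoring
#'   time.
#' @param admin_horizon Administrative censoring time.
#' @param covariate For the stratified scenario: list with elements `p1`
#'   (frequency of `z = 1`) and `hazard0`, `hazard1` (all-cause hazards by
#'   `z`). Defaults are filled in for `design_kind = "stratified"`; `NULL`
#'   otherwise.
#' @param B Number of replicates.
#' @param eval_times Evaluation grid for bias/coverage summaries.
#' @param alpha Two-sided error rate of the intervals under study.
#' @param seed Integer base seed; replicate `b` uses `seed + b`.
#' @return A `sim_scenario` object (a list).
#' @export
sim_scenario <- function(design_kind = c(
                           "random", "case_control",
                           "stratified", "ncc", "full"
                         ),
                         n = 100, m = 1, N = 1000,
                         total_hazard = 0.1, cause_split = 0.5,
                         censor_low = 0.5, censor_high = 10.5,
                         admin_horizon = 2,
                         covariate = NULL,
                         B = 1000,
                         eval_times = seq(0.1, 2, by = 0.1),
                         alpha = 0.05,
                         seed = 1L) {
  design_kind <- match.arg(design_kind)
  stopifnot(
    total_hazard > 0, cause_split > 0, cause_split < 1,
    censor_low < censor_high, B >= 1, N >= 2, alpha > 0, alpha < 1
  )
  if (design_kind == "stratified" && is.null(covariate)) {
    covariate <- list(p1 = 0.3, hazard0 = 0.08, hazard1 = 0.2)
  }
  structure(
    list(
      design_kind = design_kind, n = n, m = m, N = N,
      total_hazard = total_hazard, cause_split = cause_split,
      censor_low = censor_low, censor_high = censor_high,
      admin_horizon = admin_horizon, covariate = covariate,
      B = B, eval_times = eval_times, alpha = alpha, seed = as.integer(seed)
    ),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario> ", x$design_kind, " design; N = ", x$N, ", B = ", x$B,
    "; all-cause hazard ", x$total_hazard, ", cause split ", x$cause_split,
    "; censoring U(", x$censor_low, ", ", x$censor_high, ") + admin at ",
    x$admin_horizon, "\n",
    sep = ""
  )
  invisible(x)
}

#' True crude incidence of cause 1 under a scenario
#'
#' Closed form implied by the generator: with all-cause exponential hazard
#' \eqn{\lambda} and cause split `p`, \eqn{F_1(t) = p(1 - e^{-\lambda t})};
#' under the covariate-dependent (stratified) scenario, the mixture
#' \eqn{F_1(t) = p \sum_z P(Z = z)(1 - e^{-\lambda_z t})}.
#'
#' @param t Nonnegative time(s).
#' @param scenario A [sim_scenario()].
#' @return Numeric vector of true incidences.
#' @examples
#' true_incidence(2, sim_scenario("random")) # about 0.0906
#' @export
true_incidence <- function(t, scenario = sim_scenario("random")) {
  stopifnot(all(t >= 0))
  cv <- scenario$covariate
  if (is.null(cv)) {
    scenario$cause_split * (1 - exp(-scenario$total_hazard * t))
  } else {
    scenario$cause_split * ((1 - cv$p1) * (1 - exp(-cv$hazard0 * t)) +
      cv$p1 * (1 - exp(-cv$hazard1 * t)))
  }
}

#' Generate one phase-I cohort from a scenario
#'
#' Latent event time exponential with the scenario's all-cause hazard
#' (covariate-dependent in the stratified scenario), cause drawn
#' independently with probability `cause_split` for cause 1, censoring time
#' uniform on (`censor_low`, `censor_high`), administrative censoring at
#' `admin_horizon`. The observed record is `X = min(T, C, horizon)` and the
#' cause code 0 whenever censoring comes first.
#'
#' @inheritParams true_incidence
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream (as used inside [run_scenario()]).
#' @return A tibble with columns `id`, `time`, `cause`, `case` (observed
#'   cause-1 event by the horizon) and, in the stratified scenario, `z`.
#' @export
generate_cohort <- function(scenario, seed = NULL) {
  with_seed_maybe(seed, {
    N <- scenario$N
    cv <- scenario$covariate
    if (is.null(cv)) {
      z <- NULL
      rate <- rep(scenario$total_hazard, N)
    } else {
      z <- rbinom(N, 1, cv$p1)
      rate <- ifelse(z == 1, cv$hazard1, cv$hazard0)
    }
    tt <- rexp(N, rate)
    cause <- 1L + rbinom(N, 1, 1 - scenario$cause_split)
    cc <- runif(N, scenario$censor_low, scenario$censor_high)
    x <- pmin(tt, cc, scenario$admin_horizon)
    obs <- ifelse(tt <= pmin(cc, scenario$admin_horizon), cause, 0L)
    out <- tibble(
      id = seq_len(N), time = x, cause = as.integer(obs),
      case = as.integer(obs == 1L)
    )
    if (!is.null(z)) out$z <- z
    out
  })
}

# Draw the scenario's phase-II design from a generated cohort, using the
# current RNG stream (run_scenario seeds once per replicate).
apply_design <- function(scenario, cohort) {
  switch(scenario$design_kind,
    full = design_full(cohort),
    random = sample_random(cohort, scenario$n),
    case_control = sample_case_control(cohort, cohort$case == 1L, scenario$n),
    stratified = sample_stratified(
      cohort, interaction(cohort$z, cohort$case, drop = FALSE),
      n_per_stratum = scenario$n / 4
    ),
    ncc = sample_ncc(cohort, cause = 1, m = scenario$m)
  )
}

#' Run a simulation scenario
#'
#' For each replicate: generate a cohort, draw the phase-II sample, estimate
#' \eqn{\hat F_1(t)} with its influence-function standard error and
#' log-scale confidence interval at the evaluation grid; then aggregate
#' per-time operating characteristics across replicates: mean bias
#' \eqn{\bar{\hat F}_1(t) - F_1(t)}, mean absolute bias, relative bias
#' (mean bias over \eqn{F_1(t)}), standardized bias (mean bias over the
#' empirical SD), empirical SD, mean estimated SE, coverage (fraction of
#' defined intervals containing the truth) and mean interval length.
#' Replicates with \eqn{\hat F_1(t) = 0} at a grid time have no log-scale
#' interval there; they contribute to the bias summaries but are excluded
#' from coverage and length, with the count reported in `n_ci_missing`.
#' Replicate `b` is seeded with `seed + b`, so results are reproducible and
#' independent of `B`.
#'
#' @inheritParams true_incidence
#' @return A `twophase_sim` object with elements `summary` (per-time
#'   tibble), `replicates` (per-replicate, per-time tibble), `sizes`
#'   (realized phase-II sizes) and `scenario`. `tidy()` returns the summary,
#'   `glance()` one row, `autoplot()` the estimated-vs-empirical SE plot.
#' @export
run_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  grid <- scenario$eval_times
  B <- scenario$B
  ntime <- length(grid)
  Fm <- SEm <- LOm <- HIm <- matrix(NA_real_, B, ntime)
  n2 <- integer(B)
  n_warn <- 0L
  for (b in seq_len(B)) {
    set.seed(scenario$seed + b)
    rep_fit <- withCallingHandlers(
      {
        cohort <- generate_cohort(scenario)
        des <- apply_design(scenario, cohort)
        prep <- tp_prepare(cohort, des)
        fit <- tp_fit_one(des, prep, 1L,
          eval_times = grid,
          alpha = scenario$alpha, se = TRUE
        )
        fit$n2 <- sum(des$xi)
        fit
      },
      warning = function(w) {
        n_warn <<- n_warn + 1L
        invokeRestart("muffleWarning")
      }
    )
    Fm[b, ] <- rep_fit$F
    SEm[b, ] <- rep_fit$se_F
    LOm[b, ] <- rep_fit$conf_low
    HIm[b, ] <- rep_fit$conf_high
    n2[b] <- rep_fit$n2
  }
  truth <- true_incidence(grid, scenario)
  bias <- sweep(Fm, 2, truth)
  emp_sd <- apply(Fm, 2, stats::sd)
  covered <- sweep(LOm, 2, truth, `<=`) & sweep(HIm, 2, truth, `>=`)
  summary <- tibble(
    time = grid,
    true_F = truth,
    mean_F = colMeans(Fm),
    mean_bias = colMeans(bias),
    mean_abs_bias = colMeans(abs(bias)),
    relative_bias = colMeans(bias) / truth,
    standardized_bias = colMeans(bias) / emp_sd,
    emp_sd = emp_sd,
    mean_se = colMeans(SEm),
    coverage = colMeans(covered, na.rm = TRUE),
    mean_ci_length = colMeans(HIm - LOm, na.rm = TRUE),
    n_ci_missing = colSums(is.na(LOm))
  )
  replicates <- tibble(
    rep = rep(seq_len(B), times = ntime),
    time = rep(grid, each = B),
    cuminc = as.vector(Fm),
    std_error = as.vector(SEm),
    conf_low = as.vector(LOm),
    conf_high = as.vector(HIm)
  )
  structure(
    list(
      summary = summary, replicates = replicates, sizes = n2,
      scenario = scenario, n_warnings = n_warn
    ),
    class = "twophase_sim"
  )
}

#' Estimated versus empirical standard error
#'
#' Pairs the mean estimated SE of \eqn{\hat F_1(t)} with the empirical SD
#' across replicates at each grid time, plus their ratio (missing where the
#' empirical SD is zero). Ratios near 1 indicate the influence-function
#' variance tracks the true sampling variability.
#'
#' @param result A `twophase_sim` from [run_scenario()].
#' @return A tibble with columns `time`, `mean_se`, `emp_sd`, `ratio`.
#' @export
evaluate_se_agreement <- function(result) {
  stopifnot(inherits(result, "twophase_sim"))
  s <- result$summary
  tibble(
    time = s$time, mean_se = s$mean_se, emp_sd = s$emp_sd,
    ratio = ifelse(s$emp_sd > 0, s$mean_se / s$emp_sd, NA_real_)
  )
}

#' @export
print.twophase_sim <- function(x, ...) {
  cat("<twophase_sim> ", x$scenario$design_kind, " design, B = ",
    x$scenario$B, ", N = ", x$scenario$N,
    "; mean phase-II size ", round(mean(x$sizes), 1), "\n",
    sep = ""
  )
  print(x$summary, n = 8)
  invisible(x)
}

#' @describeIn run_scenario Per-time operating characteristics as a tibble.
#' @param x A `twophase_sim` object.
#' @param ... Unused.
#' @method tidy twophase_sim
#' @export
tidy.twophase_sim <- function(x, ...) {
  x$summary
}

#' @describeIn run_scenario One-row summary: design, B, N, mean and SD of
#'   the realized phase-II size, maximum absolute mean bias, mean coverage.
#' @method glance twophase_sim
#' @export
glance.twophase_sim <- function(x, ...) {
  tibble(
    design = x$scenario$design_kind, B = x$scenario$B, N = x$scenario$N,
    mean_n2 = mean(x$sizes), sd_n2 = stats::sd(x$sizes),
    max_abs_mean_bias = max(abs(x$summary$mean_bias)),
    mean_coverage = mean(x$summary$coverage, na.rm = TRUE)
  )
}

#' @describeIn run_scenario Estimated-vs-empirical SE scatter with the
#'   identity line.
#' @param object A `twophase_sim` object.
#' @method autoplot twophase_sim
#' @export
autoplot.twophase_sim <- function(object, ...) {
  agr <- evaluate_se_agreement(object)
  ggplot2::ggplot(agr, ggplot2::aes(x = .data$emp_sd, y = .data$mean_se)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "empirical SD across replicates",
      y = "mean estimated SE",
      title = paste0(
        "SE agreement (", object$scenario$design_kind,
        " design, B = ", object$scenario$B, ")"
      )
    ) +
    ggplot2::theme_minimal()
}
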