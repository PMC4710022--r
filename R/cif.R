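# Full estimation pipeline for one cause on a prepared sample: incidence at
# its event times, then (optionally) influence-based variance and log-scale
# CI, resolved onto `eval_times` by right-continuous lookup.
#
# Subgroup fits that borrow the overall censoring survival pass `G_ext`
# (the overall reverse-KM step), `cens` (overall censoring hazard context)
# and `prep_all` (all selected subjects: each one influences the subgroup
# estimate through G, so the influence matrix spans the full sample).
tp_fit_one <- function(selection, prep, cause, eval_times = NULL,
                       alpha = 0.05, se = TRUE, G_ext = NULL, cens = NULL,
                       prep_all = NULL) {
  cv0 <- tp_curves(prep)
  cv <- c(cv0, tp_cause_curves(cv0, prep, cause, G_ext))
  ue <- cv$tu[cv$eidx]
  Fe <- cv$F_pl[cv$eidx]
  horizon <- if (is.null(eval_times)) Inf else max(eval_times)
  if (se) {
    if (is.null(prep_all)) {
      infl <- tp_influence(prep, cv, horizon)
      zidx <- prep$idx
    } else {
      infl <- tp_influence(prep, cv, horizon,
        cens = cens,
        all = list(
          x = prep_all$x, d = prep_all$d,
          rows = match(prep$idx, prep_all$idx)
        )
      )
      zidx <- prep_all$idx
    }
    zobj <- structure(
      list(times = infl$times, z = infl$z, idx = zidx, cause = cause),
      class = "influence_matrix"
    )
    s2_I <- phase1_variance(zobj, selection)
    s2_II <- phase2_variance(zobj, selection)
    s2 <- s2_I + s2_II
  }
  times <- eval_times %||% ue
  pos <- findInterval(times, ue)
  Ft <- c(0, Fe)[pos + 1L]
  out <- list(
    times = times, F = Ft,
    n_risk = {
      idx <- findInterval(times, cv$tu, left.open = TRUE)
      c(cv$Y0, cv$Ystar_after)[idx + 1L]
    },
    n_event = c(0, cumsum(cv$dNk[cv$eidx]))[pos + 1L],
    cv = cv
  )
  if (se) {
    ipos <- findInterval(times, infl$times)
    s2_t <- c(0, s2)[ipos + 1L]
    out$sigma2_I <- c(0, s2_I)[ipos + 1L]
    out$sigma2_II <- c(0, s2_II)[ipos + 1L]
    out$var_F <- variance_of_F(Ft, s2_t)
    out$se_F <- sqrt(out$var_F)
    ci <- confidence_interval(Ft, sqrt(s2_t), alpha)
    out$conf_low <- ci$conf_low
    out$conf_high <- ci$conf_high
  }
  out
}

#' Crude cumulative incidence under a two-phase design
#'
#' The package's main fitting function: estimates the crude cumulative
#' incidence \eqn{\hat F_k(t)} of one or more causes from a phase-II sample
#' with design weights (see [crude_incidence_pl()]), together with
#' influence-function standard errors combining the phase-I and
#' Horvitz-Thompson phase-II variance contributions, and log-scale
#' confidence intervals. Optionally estimates within subgroups (e.g. a
#' genotype measured only at phase II). Subgroup fits keep the original
#' inclusion probabilities (conditional-on-selection weights) and, by
#' default, use the censoring survival \eqn{\hat G} estimated from the whole
#' sample — appropriate under the stronger independence assumption
#' \eqn{T \perp C}; set `cens_group = TRUE` to estimate \eqn{\hat G} within
#' each group instead.
#'
#' @inheritParams counting_processes
#' @param cause Cause code(s) to estimate; default all causes present.
#' @param eval_times Optional evaluation grid (right-continuous lookup);
#'   default: each cause's event times.
#' @param group Optional name of a grouping column in `data`; one curve per
#'   observed level.
#' @param alpha Two-sided error rate for the confidence intervals.
#' @param se Compute standard errors and intervals? (`TRUE` by default; the
#'   point estimate alone is much cheaper.)
#' @param cens_group Estimate the censoring survival within groups?
#' @return A `twophase_cif` object. `tidy()` returns the per-time estimates,
#'   `glance()` a one-row design summary, `autoplot()` the incidence curves.
#' @examples
#' d <- data.frame(time = 1:4, cause = c(1, 2, 0, 1))
#' fit <- cif_twophase(d, design_full(d))
#' tidy(fit)
#' glance(fit)
#' @export
cif_twophase <- function(data, selection = design_full(data), cause = NULL,
                         eval_times = NULL, group = NULL, alpha = 0.05,
                         se = TRUE, cens_group = FALSE) {
  validate_cohort(data, selection)
  if (!is.null(group) && !group %in% names(data)) {
    stop("grouping column '", group, "' not found", call. = FALSE)
  }
  if (is.null(group)) {
    prep <- tp_prepare(data, selection)
    causes <- cause %||% sort(unique(prep$d[prep$d > 0L]))
    est <- dplyr::bind_rows(lapply(causes, function(k) {
      fit <- tp_fit_one(selection, prep, k, eval_times, alpha, se)
      fit_table(fit, k, NULL, se)
    }))
  } else {
    g <- data[[group]]
    levs <- sort(unique(g[!is.na(g) & selection$xi == 1L]))
    if (!length(levs)) stop("no selected subject has an observed group", call. = FALSE)
    prep_all <- tp_prepare(data, selection)
    cv_all <- tp_curves(prep_all)
    G_ext <- cens <- NULL
    if (!cens_group) {
      j <- which(cv_all$dNc > 0)
      G_ext <- step_function(cv_all$tu[j], cv_all$G[j], v0 = 1, side = "right")
      ck <- which(cv_all$dNc > 0 & cv_all$dLc < 1)
      cens <- list(ct = cv_all$tu[ck], lamc = cv_all$dLc[ck], Y_at = cv_all$Y_at[ck])
    }
    est <- dplyr::bind_rows(lapply(levs, function(lev) {
      rows <- which(!is.na(g) & g == lev)
      prep <- tp_prepare(data, selection, rows)
      causes <- cause %||% sort(unique(prep$d[prep$d > 0L]))
      dplyr::bind_rows(lapply(causes, function(k) {
        fit <- tp_fit_one(selection, prep, k, eval_times, alpha, se,
          G_ext = G_ext, cens = cens,
          prep_all = if (!cens_group) prep_all else NULL
        )
        fit_table(fit, k, as.character(lev), se)
      }))
    }))
  }
  structure(
    list(
      estimates = est,
      design = selection,
      alpha = alpha,
      group = group,
      causes = sort(unique(est$cause)),
      n_phase1 = nrow(data),
      n_phase2 = sum(selection$xi),
      N_hat = sum(1 / selection$pi[selection$xi == 1L])
    ),
    class = "twophase_cif"
  )
}

fit_table <- function(fit, cause, group_label, se) {
  tb <- tibble(
    cause = cause, time = fit$times, n_risk = fit$n_risk,
    n_event = fit$n_event, cuminc = fit$F
  )
  if (se) {
    tb$std_error <- fit$se_F
    tb$conf_low <- fit$conf_low
    tb$conf_high <- fit$conf_high
  }
  if (!is.null(group_label)) tb <- dplyr::bind_cols(tibble(group = group_label), tb)
  tb
}

#' @export
print.twophase_cif <- function(x, ...) {
  cat("Crude cumulative incidence under a two-phase design (",
    x$design$kind, " sampling)\n",
    sep = ""
  )
  cat(
    "  phase I: N =", x$n_phase1, "  phase II: n =", x$n_phase2,
    "  HT size estimate:", format(x$N_hat, digits = 5), "\n"
  )
  cat(
    "  causes:", paste(x$causes, collapse = ", "),
    "  alpha =", x$alpha, "\n\n"
  )
  print(x$estimates, n = 10)
  invisible(x)
}

#' @describeIn cif_twophase Per-time estimates as a tibble (columns: optional
#'   `group`, `cause`, `time`, `n_risk` (modified risk set), `n_event`
#'   (weighted cause events), `cuminc`, and when `se = TRUE` `std_error`,
#'   `conf_low`, `conf_high`).
#' @param x A `twophase_cif` object.
#' @param ... Unused.
#' @method tidy twophase_cif
#' @export
tidy.twophase_cif <- function(x, ...) {
  x$estimates
}

#' @describeIn cif_twophase One-row summary: phase sizes, Horvitz-Thompson
#'   cohort-size estimate, number of causes, design label, alpha.
#' @method glance twophase_cif
#' @export
glance.twophase_cif <- function(x, ...) {
  tibble(
    n_phase1 = x$n_phase1, n_phase2 = x$n_phase2, N_hat = x$N_hat,
    n_causes = length(x$causes), design = x$design$kind, alpha = x$alpha
  )
}

#' @describeIn cif_twophase Step curves of \eqn{\hat F_k(t)} with pointwise
#'   confidence bands, faceted by cause and coloured by group.
#' @param object A `twophase_cif` object.
#' @method autoplot twophase_cif
#' @export
autoplot.twophase_cif <- function(object, ...) {
  est <- object$estimates
  has_group <- "group" %in% names(est)
  aes_base <- if (has_group) {
    ggplot2::aes(x = .data$time, y = .data$cuminc, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$time, y = .data$cuminc)
  }
  p <- ggplot2::ggplot(est, aes_base) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::facet_wrap(~cause, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "time", y = "crude cumulative incidence",
      title = paste0(
        "Weighted crude incidence (",
        object$design$kind, " phase-II sampling)"
      )
    ) +
    ggplot2::theme_minimal()
  if ("conf_low" %in% names(est)) {
    p <- p +
      ggplot2::geom_step(ggplot2::aes(y = .data$conf_low),
        linetype = "dashed", na.rm = TRUE, linewidth = 0.4
      ) +
      ggplot2::geom_step(ggplot2::aes(y = .data$conf_high),
        linetype = "dashed", na.rm = TRUE, linewidth = 0.4
      )
  }
  p
}
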