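# Core weighted competing-risks machinery.
#
# Everything is computed on the sorted phase-II sample (tp_prepare). At each
# unique observed time u the weighted risk set Y(u) counts subjects with
# X >= u, so events and censorings occurring at u are both still at risk at u
# (events-precede-censorings tie convention). The censoring survival G is the
# reverse Kaplan-Meier with design weights; the modified risk set Y*_k keeps
# subjects failing from competing causes in the risk set beyond their event,
# discounted by the conditional censoring weight G(s-)/G(X-).
tp_curves <- function(prep, cause = NULL) {
  x <- prep$x
  d <- prep$d
  w <- prep$w
  tu <- unique(x) # sorted, x is sorted
  ix <- match(x, tu)
  agg <- function(v) { # per-unique-time sums, aligned to tu
    out <- numeric(length(tu))
    a <- rowsum(v, group = ix, reorder = TRUE)
    out[as.integer(rownames(a))] <- a[, 1]
    out
  }
  w_exit <- agg(w)
  Y0 <- sum(w)
  Y_at <- Y0 - c(0, cumsum(w_exit)[-length(tu)]) # sum w over X >= tu
  dNc <- agg(w * (d == 0L))
  dNall <- agg(w * (d > 0L))
  dLc <- dNc / Y_at
  dLall <- dNall / Y_at
  G <- cumprod(1 - dLc)
  G_left <- c(1, G[-length(G)])
  S <- cumprod(1 - dLall)
  S_left <- c(1, S[-length(S)])
  out <- list(
    tu = tu, ix = ix, Y0 = Y0, Y_at = Y_at, w_exit = w_exit,
    dNc = dNc, dNall = dNall, dLc = dLc, G = G, G_left = G_left,
    S = S, S_left = S_left
  )
  if (!is.null(cause)) out <- c(out, tp_cause_curves(out, prep, cause))
  out
}

# Cause-specific pieces: modified risk set, subdistribution hazard and the
# product-limit crude incidence for one cause. `G_ext` optionally supplies
# an externally estimated censoring survival (a tp_step): subgroup fits use
# the overall-sample G by default, per the independence assumption T ⊥ C.
tp_cause_curves <- function(cv, prep, cause, G_ext = NULL) {
  x <- prep$x
  d <- prep$d
  w <- prep$w
  tu <- cv$tu
  if (is.null(G_ext)) {
    G_at <- cv$G
    G_left <- cv$G_left
    Gx_left <- cv$G_left[cv$ix] # G(X_i-)
  } else {
    G_at <- step_eval(G_ext, tu, side = "right")
    G_left <- step_eval(G_ext, tu, side = "left")
    Gx_left <- step_eval(G_ext, x, side = "left")
  }
  dNk <- numeric(length(tu))
  a <- rowsum(w * (d == cause), group = cv$ix, reorder = TRUE)
  dNk[as.integer(rownames(a))] <- a[, 1]
  comp <- d != 0L & d != cause
  compw <- ifelse(comp, w / Gx_left, 0)
  cw <- numeric(length(tu))
  a <- rowsum(compw, group = cv$ix, reorder = TRUE)
  cw[as.integer(rownames(a))] <- a[, 1]
  comp_upto <- cumsum(cw) # sum over subjects with X <= tu
  comp_before <- c(0, comp_upto[-length(tu)]) # X < tu
  Ystar_at <- cv$Y_at + G_left * comp_before
  eidx <- which(dNk > 0)
  if (any(Ystar_at[eidx] <= 0)) {
    stop("undefined increment: modified risk set is zero at a cause-", cause,
      " event time",
      call. = FALSE
    )
  }
  dLstar <- numeric(length(tu))
  dLstar[eidx] <- dNk[eidx] / Ystar_at[eidx]
  F_pl <- 1 - cumprod(1 - dLstar)
  Ystar_after <- (cv$Y_at - cv$w_exit) + G_at * comp_upto
  list(
    cause = cause, dNk = dNk, comp = comp, Gx_left = Gx_left,
    Gk_at = G_at, Gk_left = G_left,
    Ystar_at = Ystar_at, Ystar_after = Ystar_after, eidx = eidx,
    dLstar = dLstar, F_pl = F_pl
  )
}

#' Weighted censoring survival (reverse Kaplan-Meier)
#'
#' Estimates \eqn{G(t) = P(C > t)} by the product-limit estimator with the
#' roles of events and censorings swapped, using design weights:
#' \eqn{\hat G(t) = \prod_{s \le t} [1 - \hat N^c_\cdot(ds)/\hat Y_\cdot(s)]}.
#' With no censored subjects \eqn{\hat G \equiv 1}; uniform weights cancel in
#' the ratio, reproducing the unweighted reverse Kaplan-Meier.
#'
#' @inheritParams counting_processes
#' @return A [step_function()] with `v0 = 1` (cadlag).
#' @export
censoring_survival <- function(data, selection) {
  cv <- tp_curves(tp_prepare(data, selection))
  j <- which(cv$dNc > 0)
  step_function(cv$tu[j], cv$G[j], v0 = 1, side = "right")
}

#' Conditional censoring weight
#'
#' The weight \eqn{\hat G(s^-|X^-) = \hat G(s^-)/\hat G(x^-)} estimating
#' \eqn{P(C > s^- | C > x^-)}: the probability that a subject last seen at
#' `x` would still be uncensored just before `s`. Equals 1 for `s <= x` and
#' is nonincreasing in `s`. Used to discount the risk-set contribution of
#' subjects failing from competing causes.
#'
#' @param G A censoring-survival [step_function()] (from
#'   [censoring_survival()]).
#' @param s,x Numeric vectors of evaluation and conditioning times (recycled).
#' @return Numeric vector of weights.
#' @export
conditional_censoring_weight <- function(G, s, x) {
  den <- step_eval(G, x, side = "left")
  num <- step_eval(G, s, side = "left")
  if (any(den == 0 & s > x)) {
    stop("undefined weight: G(x-) = 0", call. = FALSE)
  }
  ifelse(s <= x, 1, num / den)
}

#' Modified risk set for the subdistribution hazard
#'
#' The weighted number at risk for the improper time \eqn{T^*_k} (equal to
#' `T` for cause-`k` failures, infinite otherwise):
#' \deqn{\hat Y^*_{\cdot k}(s) = \sum_i \frac{\xi_i}{\pi_i} Y_i(s) +
#'   \sum_i \frac{\xi_i}{\pi_i} \sum_{l \ne k} N_{il}(s^-)\,
#'   \hat G(s^-|X_i^-).}
#' Subjects who failed from a competing cause stay in the risk set, weighted
#' by the conditional censoring survival; before the first competing event
#' it equals the ordinary risk set, and with a single cause it reduces to it
#' everywhere. It also satisfies the identity
#' \eqn{\hat Y^*_{\cdot k}(s) = \hat Y_\cdot(s)[1-\hat F_k(s^-)]/\hat S(s^-)}
#' wherever \eqn{\hat S(s^-) > 0}.
#'
#' @inheritParams counting_processes
#' @return A [step_function()] with the left-continuous at-risk convention.
#' @export
modified_risk_set <- function(data, selection, cause) {
  cv <- tp_curves(tp_prepare(data, selection), cause)
  step_function(cv$tu, cv$Ystar_after, v0 = cv$Y0, side = "left")
}

#' Weighted cumulative subdistribution hazard
#'
#' \eqn{\hat\Lambda^*_k(t) = \int_0^t \hat N_{\cdot k}(ds)/\hat
#' Y^*_{\cdot k}(s)}: jumps only at cause-`k` event times, with increments in
#' `[0, 1]`. Under full sampling this is the classical subdistribution
#' cumulative hazard; with no competing events it is the weighted
#' Nelson-Aalen estimator of the all-cause hazard.
#'
#' @inheritParams counting_processes
#' @return A [step_function()] (cadlag, `v0 = 0`).
#' @export
subdist_hazard <- function(data, selection, cause) {
  cv <- tp_curves(tp_prepare(data, selection), cause)
  step_function(cv$tu[cv$eidx], cumsum(cv$dLstar[cv$eidx]), v0 = 0, side = "right")
}

#' Weighted overall survival
#'
#' The product-limit estimator over all-cause events with design weights:
#' \eqn{\hat S(t) = \prod_{s\le t}[1 - \hat\Lambda(ds)]} with
#' \eqn{\hat\Lambda = \sum_k \hat\Lambda_k},
#' \eqn{\hat\Lambda_k(t) = \int_0^t \hat N_{\cdot k}(ds)/\hat Y_\cdot(s)}.
#' With uniform weights this is the ordinary Kaplan-Meier estimator.
#'
#' @inheritParams counting_processes
#' @return A [step_function()] with `v0 = 1` (cadlag).
#' @export
overall_survival <- function(data, selection) {
  cv <- tp_curves(tp_prepare(data, selection))
  j <- which(cv$dNall > 0)
  step_function(cv$tu[j], cv$S[j], v0 = 1, side = "right")
}

new_incidence_estimate <- function(cause, times, F_vals, cv, se = NULL,
                                   conf_low = NULL, conf_high = NULL) {
  structure(
    list(
      cause = cause,
      times = times,
      F = step_function(times, F_vals, v0 = 0, side = "right"),
      Lambda_star = step_function(times, cumsum(cv$dLstar[cv$eidx]),
        v0 = 0, side = "right"
      ),
      Ystar = step_function(cv$tu, cv$Ystar_after, v0 = cv$Y0, side = "left"),
      G = {
        j <- which(cv$dNc > 0)
        step_function(cv$tu[j], cv$G[j], v0 = 1, side = "right")
      },
      se = se, conf_low = conf_low, conf_high = conf_high
    ),
    class = "incidence_estimate"
  )
}

#' @export
print.incidence_estimate <- function(x, ...) {
  cat("<incidence_estimate> cause ", x$cause, ", ", length(x$times),
    " jump times; F(max) = ",
    format(if (length(x$F$value)) max(x$F$value) else 0, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @method as_tibble incidence_estimate
#' @export
as_tibble.incidence_estimate <- function(x, ...) {
  out <- tibble(
    cause = x$cause, time = x$times, cuminc = x$F$value,
    cum_subdist_hazard = x$Lambda_star$value
  )
  if (!is.null(x$se)) {
    out$std_error <- x$se
    out$conf_low <- x$conf_low
    out$conf_high <- x$conf_high
  }
  out
}

#' Crude cumulative incidence, product-limit form
#'
#' The package's core estimator: the crude incidence of cause `k` in the
#' presence of competing risks from a two-phase sample,
#' \deqn{\hat F_k(t) = 1 - \prod_{s \le t}\left[1 -
#'   \hat\Lambda^*_k(ds)\right],}
#' the product-limit transform of the weighted cumulative subdistribution
#' hazard (see [subdist_hazard()]). It is algebraically equivalent to the
#' Aalen-Johansen form computed by [crude_incidence_aj()]. With no censoring
#' it reduces to the weighted proportion of cause-`k` events; with a single
#' cause, to one minus the weighted Kaplan-Meier estimator; under full
#' sampling, to the classical crude-incidence estimator.
#'
#' @inheritParams counting_processes
#' @return An `incidence_estimate`: the incidence `F`, cumulative
#'   subdistribution hazard `Lambda_star`, modified risk set `Ystar` and
#'   censoring survival `G` as [step_function()]s, with `se`/`conf_*` slots
#'   filled by the variance layer ([cif_twophase()]).
#' @examples
#' d <- data.frame(time = 1:4, cause = c(1, 2, 0, 1))
#' fit <- crude_incidence_pl(d, design_full(d), cause = 1)
#' step_eval(fit$F, c(1, 4)) # 0.25, 0.75
#' @export
crude_incidence_pl <- function(data, selection, cause) {
  cv <- tp_curves(tp_prepare(data, selection), cause)
  new_incidence_estimate(cause, cv$tu[cv$eidx], cv$F_pl[cv$eidx], cv)
}

#' Crude cumulative incidence, Aalen-Johansen form
#'
#' Computes \eqn{\hat F_k(t) = \int_0^t \hat S(s^-)\hat\Lambda_k(ds)} for
#' every cause, with \eqn{\hat S} the weighted overall survival and
#' \eqn{\hat\Lambda_k} the weighted cause-specific Nelson-Aalen estimator.
#' Mass is conserved by construction:
#' \eqn{\sum_k \hat F_k(t) + \hat S(t) = 1} at every `t`, and each curve
#' agrees with the product-limit form of [crude_incidence_pl()].
#'
#' @inheritParams counting_processes
#' @return A named list of `incidence_estimate` objects, one per cause code
#'   present in the selected data.
#' @export
crude_incidence_aj <- function(data, selection) {
  prep <- tp_prepare(data, selection)
  causes <- sort(unique(prep$d[prep$d > 0L]))
  cv0 <- tp_curves(prep)
  out <- lapply(causes, function(k) {
    cvk <- c(cv0, tp_cause_curves(cv0, prep, k))
    dLk <- cvk$dNk / cvk$Y_at
    F_aj <- cumsum(cvk$S_left * dLk)
    new_incidence_estimate(k, cvk$tu[cvk$eidx], F_aj[cvk$eidx], cvk)
  })
  stats::setNames(out, paste0("cause", causes))
}
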