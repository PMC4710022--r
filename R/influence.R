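# Influence functions and two-phase variance.
#
# The influence value z*_ik(t) is the derivative of the weighted cumulative
# subdistribution hazard with respect to subject i's design weight w_i
# (Demnati-Rao linearisation):
#
#   z*_ik(t) = int_0^t [N_ik(ds) Y*(s) - (dY*(s)/dw_i) Nhat_k(ds)] / Y*(s)^2
#
# with dY*(s)/dw_i = Y_i(s)
#   + I(X_i <= s-, eps_i not in {0, k}) G(s-)/G(X_i- ^ s-)
#   - sum_j xi_j w_j I(X_j <= s-, eps_j not in {0,k}) [G(s-)/G(X_j-)] *
#       sum_{c in [X_j, s)} [N^c_i(dc) - lambda^c(c) Y_i(c)] /
#                           [Yhat(c) (1 - lambda^c(c))].
#
# The last term is the exact derivative of the product-limit censoring
# survival ratio: raising the weight of a subject censored at c lowers G
# beyond c, so the term carries a minus sign, and each increment carries the
# finite-sample product-limit factor 1/(1 - lambda^c(c)). This makes z the
# exact Gateaux derivative of the estimator, so it matches a
# finite-difference weight perturbation to O(h) on any fixture.

# z matrix at cause-k event times <= horizon. By default rows follow prep
# order (selected subjects sorted by time) and the censoring hazard comes
# from the same sample. For subgroup fits that borrow the overall censoring
# survival, `cens` supplies the censoring sample's jump times / hazard /
# risk set and `all` the full set of subjects forming the rows of z (each
# influences the estimate through G even when outside the subgroup);
# `all$rows` maps prep-order subjects onto z rows.
tp_influence <- function(prep, cv, horizon = Inf, cens = NULL, all = NULL) {
  x <- prep$x
  d <- prep$d
  w <- prep$w
  if (is.null(cens)) {
    cidx <- which(cv$dNc > 0 & cv$dLc < 1) # dLc = 1 kills G; ratios past it are 0
    cens <- list(ct = cv$tu[cidx], lamc = cv$dLc[cidx], Y_at = cv$Y_at[cidx])
  }
  if (is.null(all)) {
    all <- list(x = x, d = d, rows = seq_along(x))
  }
  m <- length(all$x)
  keep <- cv$tu[cv$eidx] <= horizon
  eidx <- cv$eidx[keep]
  ue <- cv$tu[eidx]
  D <- length(ue)
  if (D == 0L) {
    return(list(times = numeric(0), z = matrix(0, m, 0)))
  }
  Ystar_e <- cv$Ystar_at[eidx]
  dLs_e <- cv$dLstar[eidx]
  G_left_e <- cv$Gk_left[eidx] # G(s-) at event times (overall G if borrowed)
  dW <- matrix(0, m, D)
  compi <- cv$comp
  dW[all$rows, ] <- outer(x, ue, `>=`) +
    outer(ifelse(compi, 1 / cv$Gx_left, 0), G_left_e) * outer(x, ue, `<`)
  jc <- which(compi)
  if (length(cens$ct) && length(jc)) {
    ct <- cens$ct
    den <- cens$Y_at * (1 - cens$lamc)
    num <- outer(all$x, ct, `==`) * (all$d == 0L) -
      sweep(outer(all$x, ct, `>=`), 2, cens$lamc, `*`)
    Mi <- sweep(num, 2, den, `/`)
    q <- length(ct)
    Mcum <- Mi %*% upper.tri(diag(q), diag = TRUE) # row-wise cumsum
    Mleft <- function(t) { # M_i(0, t-): censor jumps strictly before t
      cbind(0, Mcum)[, 1L + findInterval(t, ct, left.open = TRUE), drop = FALSE]
    }
    coefJ <- outer(w[jc] / cv$Gx_left[jc], G_left_e) * outer(x[jc], ue, `<`)
    Ve <- colSums(coefJ) # competing part of Ystar at ue
    dW <- dW - (sweep(Mleft(ue), 2, Ve, `*`) - Mleft(x[jc]) %*% coefJ)
  }
  Ev <- matrix(0, m, D)
  Ev[all$rows, ] <- outer(x, ue, `==`) * (d == cv$cause)
  zinc <- sweep(Ev, 2, 1 / Ystar_e, `*`) - sweep(dW, 2, dLs_e / Ystar_e, `*`)
  z <- zinc %*% upper.tri(diag(D), diag = TRUE)
  list(times = ue, z = z)
}

#' Influence of one subject on the censoring survival
#'
#' The censoring-process term entering the influence function:
#' \deqn{M^c_i(s, t) = \int_s^t \frac{N^c_i(du) - \hat\lambda^c(u) Y_i(u)}
#'   {\hat Y_\cdot(u)},}
#' with \eqn{\hat\lambda^c(u) = \hat N^c_\cdot(du)/\hat Y_\cdot(u)} the
#' weighted censoring hazard. It is additive over abutting intervals and zero
#' when no censoring mass falls in `(s, t]` for a subject at risk throughout.
#' `method = "martingale"` returns this plug-in form; `method = "exact"`
#' rescales each increment by \eqn{1/[1-\hat\lambda^c(u)]}, which makes
#' \eqn{-M^c_i(s,t)} the exact derivative of
#' \eqn{\log[\hat G(t^-)/\hat G(s^-)]} with respect to \eqn{w_i} for the
#' product-limit \eqn{\hat G}; the exact form (with its sign) is what
#' [influence_matrix()] uses internally.
#'
#' @inheritParams counting_processes
#' @param i Cohort row index of the subject (must be selected).
#' @param s,t Interval bounds, `s <= t`. Censoring jumps in `(s, t]` with the
#'   convention that a jump at exactly `s` is excluded and one at `t` is
#'   included.
#' @param method `"martingale"` (plug-in integrand, as the influence
#'   expansion is usually written) or `"exact"` (product-limit derivative
#'   scaling).
#' @return A single numeric value.
#' @export
censoring_influence <- function(data, selection, i, s, t,
                                method = c("martingale", "exact")) {
  method <- match.arg(method)
  stopifnot(s <= t)
  prep <- tp_prepare(data, selection)
  pos <- match(i, prep$idx)
  if (is.na(pos)) stop("subject ", i, " is not selected", call. = FALSE)
  cv <- tp_curves(prep)
  cidx <- which(cv$dNc > 0)
  if (!length(cidx)) {
    return(0)
  }
  ct <- cv$tu[cidx]
  lamc <- cv$dLc[cidx]
  use <- ct > s & ct <= t
  if (!any(use)) {
    return(0)
  }
  xi <- prep$x[pos]
  di <- prep$d[pos]
  inc <- (as.numeric(xi == ct & di == 0L) - lamc * (xi >= ct)) / cv$Y_at[cidx]
  if (method == "exact") {
    if (any(use & lamc >= 1)) {
      stop("undefined: censoring hazard reaches 1 inside the interval", call. = FALSE)
    }
    inc <- inc / (1 - lamc)
  }
  sum(inc[use])
}

#' Influence matrix of the weighted subdistribution hazard
#'
#' Computes \eqn{z^*_{ik}(t)}, the influence of each selected subject on
#' \eqn{\hat\Lambda^*_k(t)}, at every cause-`k` event time up to `horizon`.
#' The value is the exact derivative of the estimator with respect to the
#' subject's design weight, including the term propagating through the
#' estimated censoring survival \eqn{\hat G} (see [censoring_influence()]).
#' With a single cause the \eqn{\hat G} term vanishes and `z` reduces to the
#' classical Nelson-Aalen influence residuals.
#'
#' @inheritParams counting_processes
#' @param horizon Latest event time to include (default all).
#' @return An `influence_matrix` object: `times` (grid), `z` (one row per
#'   selected subject, one column per grid time), `idx` (cohort row index of
#'   each z row) and `cause`.
#' @export
influence_matrix <- function(data, selection, cause, horizon = Inf) {
  prep <- tp_prepare(data, selection)
  cv <- tp_curves(prep, cause)
  infl <- tp_influence(prep, cv, horizon)
  structure(
    list(times = infl$times, z = infl$z, idx = prep$idx, cause = cause),
    class = "influence_matrix"
  )
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat("<influence_matrix> cause ", x$cause, ": ", nrow(x$z), " subjects x ",
    length(x$times), " event times\n",
    sep = ""
  )
  invisible(x)
}

#' Phase-II (design) variance of the weighted subdistribution hazard
#'
#' Horvitz-Thompson variance of the weighted influence-function total:
#' \deqn{\hat\sigma^2_{k\,II}(t) = \sum_i\sum_j \left[
#'   \frac{z_i(t) z_j(t)}{\pi_i \pi_j} - \frac{z_i(t) z_j(t)}{\pi_{ij}}
#' \right],}
#' summing over selected pairs. It is exactly zero under a census
#' (\eqn{\pi \equiv 1}): all remaining uncertainty then belongs to phase I.
#' Small-sample estimates can dip below zero and are floored at 0 with a
#' warning.
#'
#' @param z An [influence_matrix()].
#' @param selection The `two_phase_design` the matrix was computed under.
#' @return Numeric vector of per-time variances (one per `z$times`).
#' @export
phase2_variance <- function(z, selection) {
  stopifnot(inherits(z, "influence_matrix"))
  pi <- selection$pi[z$idx]
  P <- pairwise_matrix(selection, z$idx)
  if (any(P <= 0)) stop("invalid design: nonpositive pairwise probability", call. = FALSE)
  A <- 1 / outer(pi, pi) - 1 / P
  out <- colSums((A %*% z$z) * z$z)
  if (any(out < 0)) {
    neg <- min(out)
    if (neg < -1e-8 * max(abs(out), 1e-12)) {
      warning("negative Horvitz-Thompson phase-II variance floored at 0",
        call. = FALSE
      )
    }
    out <- pmax(out, 0)
  }
  out
}

#' Phase-I (sampling-from-population) variance
#'
#' The Horvitz-Thompson estimate of the i.i.d. phase-I variance of the
#' influence total: \eqn{\hat\sigma^2_{k\,I}(t) = \sum_i \xi_i
#' z_i(t)^2/\pi_i}. This is the irreducible uncertainty that would remain if
#' the whole cohort were sampled at phase II.
#'
#' @inheritParams phase2_variance
#' @return Numeric vector of per-time variances.
#' @export
phase1_variance <- function(z, selection) {
  stopifnot(inherits(z, "influence_matrix"))
  pi <- selection$pi[z$idx]
  colSums(z$z^2 / pi)
}

#' Variance of the crude incidence from the hazard-scale variance
#'
#' The one-to-one product-limit relation between \eqn{F_k} and
#' \eqn{\Lambda^*_k} gives
#' \eqn{\widehat{var}[\hat F_k(t)] = [1-\hat F_k(t)]^2 \hat\sigma^2_k(t)},
#' zero wherever \eqn{\hat F_k = 1}.
#'
#' @param F Crude-incidence values: a numeric vector or an
#'   `incidence_estimate` (its jump-time values are used).
#' @param sigma2 Per-time total variance \eqn{\hat\sigma^2_k(t)} of the
#'   cumulative subdistribution hazard (phase I + phase II), aligned to `F`.
#' @return Numeric vector of variances of \eqn{\hat F_k(t)}.
#' @export
variance_of_F <- function(F, sigma2) {
  fv <- if (inherits(F, "incidence_estimate")) F$F$value else F
  stopifnot(length(fv) == length(sigma2), all(sigma2 >= 0))
  (1 - fv)^2 * sigma2
}

#' Log-scale confidence interval for the crude incidence
#'
#' Two-sided interval computed on the logarithm of \eqn{\hat F_k(t)}:
#' \deqn{\exp\left\{\log \hat F_k(t) \pm q_{\alpha/2}
#'   \frac{1-\hat F_k(t)}{\hat F_k(t)} \hat\sigma_k(t)\right\},}
#' with `q` the standard-normal quantile and \eqn{\hat\sigma_k(t)} the
#' standard deviation of the cumulative subdistribution hazard. Bounds are
#' clipped to `[0, 1]`; at times where \eqn{\hat F_k(t) = 0} the interval is
#' undefined and reported as `NA`.
#'
#' @inheritParams variance_of_F
#' @param sigma Per-time standard deviation \eqn{\hat\sigma_k(t)}
#'   (hazard scale), aligned to `F`.
#' @param alpha Two-sided error rate in (0, 1); default 0.05.
#' @return A tibble with columns `conf_low`, `conf_high`.
#' @export
confidence_interval <- function(F, sigma, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  fv <- if (inherits(F, "incidence_estimate")) F$F$value else F
  stopifnot(length(fv) == length(sigma))
  q <- qnorm(1 - alpha / 2)
  half <- q * (1 - fv) / fv * sigma
  low <- ifelse(fv > 0, pmin(1, pmax(0, fv * exp(-half))), NA_real_)
  high <- ifelse(fv > 0, pmin(1, pmax(0, fv * exp(half))), NA_real_)
  tibble(conf_low = low, conf_high = high)
}
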