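#' Two-phase sampling designs
#'
#' A `two_phase_design` records, for every row of the phase-I cohort, the
#' phase-II selection indicator \eqn{\xi_i} and the first-order inclusion
#' probability \eqn{\pi_i = P(\xi_i = 1 | \mathrm{phase\ I\ data})}, together
#' with the rule giving pairwise probabilities \eqn{\pi_{ij}}. Inverse
#' probabilities \eqn{w_i = 1/\pi_i} act as design weights in all estimators;
#' \eqn{\pi_{ij}} enters only the Horvitz-Thompson phase-II variance.
#'
#' Constructors:
#' * `design_full()` — census: everyone selected with \eqn{\pi \equiv 1};
#'   reproduces the classical full-cohort analysis.
#' * `design_custom()` — user-supplied `xi` and `pi` (e.g. read from a file);
#'   pairwise probabilities default to \eqn{\pi_i \pi_j} unless a matrix is
#'   given.
#' * [sample_random()], [sample_stratified()], [sample_case_control()],
#'   [sample_ncc()] — draw a phase-II sample from the cohort.
#'
#' @param data Phase-I cohort data frame.
#' @param xi Vector of 0/1 selection indicators aligned to `data` rows
#'   (logical accepted).
#' @param pi Numeric vector of first-order inclusion probabilities in (0, 1],
#'   required wherever `xi == 1`.
#' @param pairwise Optional symmetric matrix of \eqn{\pi_{ij}} (full
#'   `N x N`), used by `design_custom()`.
#' @param label Design label stored on the object.
#' @return A `two_phase_design` object.
#' @examples
#' d <- data.frame(time = 1:4, cause = c(1, 2, 0, 1))
#' design_full(d)
#' design_custom(d, xi = c(1, 1, 0, 1), pi = c(.5, .5, NA, .5))
#' @export
design_full <- function(data) {
  new_design(rep(1L, nrow(data)), rep(1, nrow(data)), kind = "full")
}

#' @rdname design_full
#' @export
design_custom <- function(data, xi, pi, pairwise = NULL, label = "custom") {
  xi <- as.integer(as.logical(xi))
  if (length(xi) != nrow(data) || length(pi) != length(xi)) {
    stop("`xi` and `pi` must align with the cohort rows", call. = FALSE)
  }
  if (!is.null(pairwise)) {
    if (!is.matrix(pairwise) || !all(dim(pairwise) == length(xi))) {
      stop("`pairwise` must be an N x N matrix", call. = FALSE)
    }
    if (max(abs(pairwise - t(pairwise)), na.rm = TRUE) > 1e-12) {
      stop("`pairwise` must be symmetric", call. = FALSE)
    }
  }
  new_design(xi, pi, kind = label, params = list(pairwise = pairwise))
}

new_design <- function(xi, pi, kind, params = list(), seed = NULL) {
  sel <- xi == 1L
  if (any(is.na(pi[sel]) | pi[sel] <= 0 | pi[sel] > 1)) {
    stop("invalid design: pi must be in (0, 1] for every selected subject",
      call. = FALSE
    )
  }
  structure(
    list(
      xi = as.integer(xi), pi = as.numeric(pi), kind = kind,
      params = params, seed = seed
    ),
    class = "two_phase_design"
  )
}

#' @export
print.two_phase_design <- function(x, ...) {
  cat("<two_phase_design> kind = ", x$kind, "; N = ", length(x$xi),
    ", n selected = ", sum(x$xi),
    "; sum(1/pi) over selected = ",
    format(sum(1 / x$pi[x$xi == 1L]), digits = 5), "\n",
    sep = ""
  )
  invisible(x)
}

#' @method as_tibble two_phase_design
#' @export
as_tibble.two_phase_design <- function(x, ...) {
  tibble(xi = x$xi, pi = x$pi)
}

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Simple random phase-II sample
#'
#' Draws `n` of the `N` cohort members without replacement, all with equal
#' probability: \eqn{\pi_i = n/N} and, for \eqn{i \ne j},
#' \eqn{\pi_{ij} = n(n-1)/(N(N-1))}.
#'
#' @param data Phase-I cohort data frame.
#' @param n Phase-II sample size (`n <= N`).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A `two_phase_design`.
#' @export
sample_random <- function(data, n, seed = NULL) {
  N <- nrow(data)
  if (n < 1 || n > N) stop("invalid design: need 1 <= n <= N", call. = FALSE)
  sel <- with_seed_maybe(seed, sample.int(N, n))
  xi <- integer(N)
  xi[sel] <- 1L
  new_design(xi, rep(n / N, N),
    kind = "random",
    params = list(n = n, N = N), seed = seed
  )
}

#' Stratified phase-II sample
#'
#' Independent simple random samples without replacement within strata:
#' \eqn{\pi_i = n_s/N_s} for subjects of stratum `s`;
#' \eqn{\pi_{ij} = n_s(n_s-1)/(N_s(N_s-1))} within a stratum and
#' \eqn{\pi_i \pi_j} across strata. A quota exceeding its stratum size is
#' capped at the stratum size (the whole stratum enters with \eqn{\pi = 1}),
#' with a warning.
#'
#' @param data Phase-I cohort data frame.
#' @param strata Stratum labels: a column name in `data`, a vector aligned to
#'   rows, or a function of `data` returning labels.
#' @param n_per_stratum Either a single quota applied to every stratum or a
#'   named vector of per-stratum quotas.
#' @param seed Optional integer seed.
#' @return A `two_phase_design`.
#' @export
sample_stratified <- function(data, strata, n_per_stratum, seed = NULL) {
  lab <- resolve_labels(data, strata, "strata")
  levs <- sort(unique(as.character(lab)))
  lab <- as.character(lab)
  ns <- resolve_quota(n_per_stratum, levs)
  N <- nrow(data)
  xi <- integer(N)
  pi <- numeric(N)
  with_seed_maybe(seed, {
    for (s in levs) {
      rows <- which(lab == s)
      Ns <- length(rows)
      if (!Ns) stop("invalid design: empty stratum '", s, "'", call. = FALSE)
      q <- ns[[s]]
      if (q < 1) stop("invalid design: stratum quota must be >= 1", call. = FALSE)
      if (q > Ns) {
        warning("stratum '", s, "' has only ", Ns, " subjects; quota ", q,
          " capped at ", Ns,
          call. = FALSE
        )
        q <- Ns
      }
      take <- if (q == Ns) rows else rows[sample.int(Ns, q)]
      xi[take] <- 1L
      pi[rows] <- q / Ns
    }
  })
  tab <- table(factor(lab, levels = levs))
  new_design(xi, pi,
    kind = "stratified",
    params = list(
      stratum = lab,
      N_s = as.numeric(tab),
      n_s = pmin(vapply(levs, function(s) ns[[s]], 1), as.numeric(tab)),
      levels = levs
    ),
    seed = seed
  )
}

#' Case-control phase-II sample
#'
#' Samples `n/2` cases and `n/2` controls without replacement, where "case"
#' is defined by a user predicate (typically: observed event of the cause of
#' interest by a horizon time). Delegates to [sample_stratified()] with the
#' case indicator as the stratum, so \eqn{\pi} is `n/2` over the number of
#' cases (controls) and quotas are capped at the stratum sizes.
#'
#' @param data Phase-I cohort data frame.
#' @param case Case indicator: a logical column name, a logical vector
#'   aligned to rows, or a predicate function of `data`.
#' @param n Total phase-II size; must be even.
#' @param seed Optional integer seed.
#' @return A `two_phase_design` (kind `"case_control"`).
#' @export
sample_case_control <- function(data, case, n, seed = NULL) {
  if (n %% 2 != 0) stop("invalid design: `n` must be even", call. = FALSE)
  cc <- as.logical(resolve_labels(data, case, "case"))
  if (!any(cc) || all(cc)) {
    stop("invalid design: need at least one case and one control", call. = FALSE)
  }
  des <- sample_stratified(data, ifelse(cc, "case", "control"),
    n_per_stratum = n / 2, seed = seed
  )
  des$kind <- "case_control"
  des
}

#' Nested case-control phase-II sample with Samuelsen weights
#'
#' Risk-set sampling: every subject failing from the target cause (a "case")
#' is selected with \eqn{\pi = 1}; at each case's event time \eqn{t_j}, `m`
#' controls are drawn uniformly without replacement from the subjects still
#' under observation past \eqn{t_j} (no event of any cause and uncensored:
#' \eqn{X_i > t_j}). A subject may be drawn at several case times but is
#' selected once. For a never-case subject the inclusion probability is
#' Samuelsen's
#' \deqn{\pi_i = 1 - \prod_{j:\, t_j < X_i} \left[1 - m/R^-(t_j)\right],}
#' where \eqn{R^-(t_j)} is the number of eligible controls at \eqn{t_j}
#' (risk-set size minus the case), and the per-time draw probability is
#' capped at 1 when fewer than `m` controls are available. Case times with an
#' empty control pool are skipped with a message. Pairwise probabilities are
#' exact under the sampling mechanism (independent draws across case times):
#' \eqn{\pi_{ij} = \pi_i + \pi_j - 1 + P(\xi_i = 0, \xi_j = 0)}, the last
#' term a closed-form product over the case times at which one or both
#' subjects are at risk; a pair involving a case has \eqn{\pi_{ij}} equal to
#' the other member's \eqn{\pi}.
#'
#' @param data Phase-I cohort data frame.
#' @param cause Target cause code defining cases.
#' @param m Number of controls per case (>= 1).
#' @param seed Optional integer seed.
#' @return A `two_phase_design` (kind `"ncc"`).
#' @export
sample_ncc <- function(data, cause, m, seed = NULL) {
  stopifnot(m >= 1)
  validate_cohort(data)
  x <- data$time
  d <- data$cause
  case <- which(!is.na(d) & d == cause)
  if (!length(case)) {
    stop("invalid design: no event of cause ", cause, " in the cohort", call. = FALSE)
  }
  N <- nrow(data)
  xi <- integer(N)
  xi[case] <- 1L
  tc <- sort(x[case])
  with_seed_maybe(seed, {
    for (tj in tc) {
      pool <- which(x > tj)
      if (!length(pool)) {
        message("nested case-control: empty risk set past t = ", tj, "; no control drawn")
        next
      }
      take <- if (length(pool) <= m) pool else pool[sample.int(length(pool), m)]
      xi[take] <- 1L
    }
  })
  # Samuelsen inclusion probabilities for never-case subjects:
  #   pi_i = 1 - prod_{j: t_j < X_i} [1 - m/R-(t_j)]
  # and the exact joint probabilities for the Horvitz-Thompson variance:
  # with independent draws across case times,
  #   P(neither i nor j ever drawn) = prod_j q_j, where q_j is
  #   (1 - m/E_j)(1 - m/(E_j - 1)) while both are at risk and (1 - m/E_j)
  #   while only the longer-surviving one is, so
  #   pi_ij = pi_i + pi_j - 1 + exp(A[l_min] + B[l_max] - B[l_min])
  # with l_i the number of case times before X_i and A, B the cumulative
  # log-products of the two-at-risk and one-at-risk terms.
  elig <- vapply(tc, function(tj) sum(x > tj), 0) # eligible controls at each case time
  pdraw <- ifelse(elig > 0, pmin(1, m / elig), 0)
  logq <- cumsum(log1p(-pdraw)) # log prod_{l<=j} (1 - p_l)
  nprior <- findInterval(x, tc, left.open = TRUE) # case times strictly before X_i
  pi <- 1 - exp(c(0, logq)[nprior + 1L])
  pi[case] <- 1
  pi <- pmin(pi, 1)
  q2 <- ifelse(elig >= 2, pmax(0, (1 - m / elig) * (1 - m / (elig - 1))), 0)
  new_design(xi, pi,
    kind = "ncc",
    params = list(
      m = m, cause = cause,
      is_case = seq_len(N) %in% case, lcount = nprior,
      A = cumsum(log(q2)), B = logq
    ),
    seed = seed
  )
}

# Exact Samuelsen joint inclusion probability for two cohort rows under the
# nested case-control design; cases are included with certainty, so a pair
# involving a case has pi_ij = pi of the other member.
ncc_pairwise <- function(selection, i, j) {
  p <- selection$params
  pi <- selection$pi
  if (p$is_case[i] || p$is_case[j]) {
    return(min(pi[i], pi[j]))
  }
  lmin <- min(p$lcount[i], p$lcount[j])
  lmax <- max(p$lcount[i], p$lcount[j])
  A0 <- c(0, p$A)
  B0 <- c(0, p$B)
  max(pi[i] + pi[j] - 1 + exp(A0[lmin + 1L] + B0[lmax + 1L] - B0[lmin + 1L]), 0)
}

resolve_labels <- function(data, spec, what) {
  out <- if (is.function(spec)) {
    spec(data)
  } else if (is.character(spec) && length(spec) == 1 && spec %in% names(data)) {
    data[[spec]]
  } else {
    spec
  }
  if (length(out) != nrow(data)) {
    stop("`", what, "` does not resolve to one label per cohort row", call. = FALSE)
  }
  if (anyNA(out)) stop("`", what, "` labels contain missing values", call. = FALSE)
  out
}

resolve_quota <- function(n_per_stratum, levs) {
  if (is.null(names(n_per_stratum))) {
    if (length(n_per_stratum) != 1) {
      stop("unnamed `n_per_stratum` must be a single quota", call. = FALSE)
    }
    stats::setNames(rep(n_per_stratum, length(levs)), levs)
  } else {
    miss <- setdiff(levs, names(n_per_stratum))
    if (length(miss)) stop("no quota for stratum '", miss[1], "'", call. = FALSE)
    n_per_stratum[levs]
  }
}

#' Pairwise inclusion probability
#'
#' Returns \eqn{\pi_{ij}} for two (selected) cohort rows under the design's
#' rule: the without-replacement joint probability for random and stratified
#' (hence case-control) designs, \eqn{\pi_i \pi_j} across independent
#' strata, the exact Samuelsen joint probability for nested case-control
#' (see [sample_ncc()]), the supplied table for custom designs, and
#' \eqn{\pi_i} on the diagonal.
#'
#' @param selection A `two_phase_design`.
#' @param i,j Row indices into the cohort (1-based); both must be selected.
#' @return A single probability.
#' @export
pairwise_probability <- function(selection, i, j) {
  stopifnot(inherits(selection, "two_phase_design"))
  if (selection$xi[i] != 1L || selection$xi[j] != 1L) {
    stop("pairwise probability requested for an unselected subject", call. = FALSE)
  }
  if (i == j) {
    return(selection$pi[i])
  }
  p <- selection$params
  switch(selection$kind,
    full = 1,
    random = p$n * (p$n - 1) / (p$N * (p$N - 1)),
    stratified = ,
    case_control = {
      si <- p$stratum[i]
      sj <- p$stratum[j]
      if (si == sj) {
        k <- match(si, p$levels)
        unname(p$n_s[k] * (p$n_s[k] - 1) / (p$N_s[k] * (p$N_s[k] - 1)))
      } else {
        selection$pi[i] * selection$pi[j]
      }
    },
    ncc = ncc_pairwise(selection, i, j),
    {
      if (!is.null(p$pairwise)) p$pairwise[i, j] else selection$pi[i] * selection$pi[j]
    }
  )
}

# Dense pi_ij matrix over the *selected* rows, in the order given by `idx`
# (row indices into the cohort). Used by the Horvitz-Thompson variance.
pairwise_matrix <- function(selection, idx) {
  m <- length(idx)
  pi <- selection$pi[idx]
  p <- selection$params
  P <- switch(selection$kind,
    full = matrix(1, m, m),
    random = matrix(p$n * (p$n - 1) / (p$N * (p$N - 1)), m, m),
    stratified = ,
    case_control = {
      k <- match(p$stratum[idx], p$levels)
      within <- (p$n_s * (p$n_s - 1) / (p$N_s * (p$N_s - 1)))[k]
      same <- outer(k, k, `==`)
      out <- outer(pi, pi)
      W <- matrix(within, m, m) # value for row's stratum
      out[same] <- W[same]
      out
    },
    ncc = {
      l <- p$lcount[idx]
      A0 <- c(0, p$A)
      B0 <- c(0, p$B)
      Lmin <- outer(l, l, pmin)
      Lmax <- outer(l, l, pmax)
      P <- outer(pi, pi, `+`) - 1 +
        exp(A0[Lmin + 1L] + B0[Lmax + 1L] - B0[Lmin + 1L])
      anycase <- outer(p$is_case[idx], p$is_case[idx], `|`)
      P[anycase] <- outer(pi, pi, pmin)[anycase]
      pmax(P, 1e-12)
    },
    {
      if (!is.null(p$pairwise)) p$pairwise[idx, idx, drop = FALSE] else outer(pi, pi)
    }
  )
  diag(P) <- pi
  P
}
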