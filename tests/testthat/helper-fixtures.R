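# Shared fixtures and independent oracles, all generated in code.

# The canonical hand-checkable cohort: cause-1 events at t = 1 and 4,
# a competing (cause-2) event at t = 2, a censoring at t = 3.
fixture4 <- function() {
  data.frame(id = 1:4, time = 1:4, cause = c(1L, 2L, 0L, 1L))
}

# Random weighted competing-risks fixture with continuous (tie-free) times.
random_fixture <- function(n = 12, n_causes = 2, seed = 1, p_censor = 0.3) {
  withr::with_seed(seed, {
    data.frame(
      id = seq_len(n),
      time = round(stats::runif(n, 0.1, 10), 6),
      cause = ifelse(
        stats::runif(n) < p_censor, 0L,
        sample.int(n_causes, n, replace = TRUE)
      )
    )
  })
}

random_weights <- function(n, seed = 1) {
  withr::with_seed(seed, stats::runif(n, 0.2, 1))
}

# Independent brute-force classical Aalen-Johansen estimator (unweighted,
# full cohort): direct loop over the sorted unique times.
brute_aj <- function(time, cause, k) {
  ut <- sort(unique(time))
  S <- 1
  F <- 0
  Fv <- numeric(length(ut))
  for (j in seq_along(ut)) {
    u <- ut[j]
    at_risk <- sum(time >= u)
    dk <- sum(time == u & cause == k)
    dall <- sum(time == u & cause > 0)
    F <- F + S * dk / at_risk
    S <- S * (1 - dall / at_risk)
    Fv[j] <- F
  }
  list(time = ut, F = Fv)
}

# Finite-difference influence oracle: d Lambda*_k(t) / d w_i by perturbing
# subject i's weight in an all-selected design.
fd_influence <- function(data, pi, i, times, cause = 1, h = 1e-6) {
  n <- nrow(data)
  lam <- function(pv) {
    des <- design_custom(data, xi = rep(1, n), pi = pv)
    L <- subdist_hazard(data, des, cause)
    step_eval(L, times)
  }
  base <- lam(pi)
  pert <- pi
  pert[i] <- 1 / (1 / pi[i] + h)
  (lam(pert) - base) / h
}
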