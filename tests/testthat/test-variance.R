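test_that("censoring influence matches the hand-computed fixture and is additive", {
  d <- fixture4()
  des <- design_full(d)
  # single censoring jump at t = 3: lambda_c = 1/2, risk set 2
  expect_equal(censoring_influence(d, des, i = 3, s = 0, t = 4), (1 - 1 / 2) / 2)
  # subject at risk past t with no censoring mass in (s, t]
  expect_equal(censoring_influence(d, des, i = 4, s = 0, t = 2.9), 0)
  # additive over abutting intervals
  m1 <- censoring_influence(d, des, 4, 0, 2)
  m2 <- censoring_influence(d, des, 4, 2, 4)
  expect_equal(censoring_influence(d, des, 4, 0, 4), m1 + m2)
  expect_error(censoring_influence(d, des, 5, 0, 4), "not selected")
})

test_that("exact censoring influence is the derivative of the censoring-survival ratio", {
  n <- 10
  d <- random_fixture(n, seed = 21, p_censor = 0.4)
  pi <- random_weights(n, seed = 22)
  des <- design_custom(d, xi = rep(1, n), pi = pi)
  s <- 1
  t <- 9
  ratio <- function(pv) {
    G <- censoring_survival(d, design_custom(d, rep(1, n), pv))
    step_eval(G, t, side = "left") / step_eval(G, s, side = "left")
  }
  h <- 1e-7
  for (i in c(1, 4, 8)) {
    pert <- pi
    pert[i] <- 1 / (1 / pi[i] + h)
    fd <- (ratio(pert) - ratio(pi)) / h
    # d/dw log ratio = -M_exact over censor jumps in (s-, t-) boundaries [s, t)
    mex <- censoring_influence(d, des, i, s - 1e-9, t - 1e-9, method = "exact")
    expect_equal(fd, -ratio(pi) * mex, tolerance = 1e-5)
  }
})

test_that("influence values equal finite-difference weight perturbations", {
  for (seed in c(1, 2, 3)) {
    n <- 8
    d <- random_fixture(n, seed = seed, p_censor = 0.35)
    pi <- if (seed == 1) rep(1, n) else random_weights(n, seed + 40)
    des <- design_custom(d, xi = rep(1, n), pi = pi)
    z <- influence_matrix(d, des, cause = 1)
    expect_gt(length(z$times), 0)
    for (i in seq_len(n)) {
      fd <- fd_influence(d, pi, i, z$times, cause = 1)
      zi <- z$z[match(i, z$idx), ]
      denom <- pmax(abs(fd), 1e-4)
      expect_lt(max(abs(fd - zi) / denom), 1e-4)
    }
  }
})

test_that("weight-scale invariance: weighted influence values sum to zero", {
  # Lambda*_k is invariant to rescaling all weights, so sum_i w_i z_i = 0
  for (seed in 4:8) {
    n <- 12
    d <- random_fixture(n, seed = seed)
    pi <- random_weights(n, seed + 10)
    des <- design_custom(d, xi = rep(1, n), pi = pi)
    z <- influence_matrix(d, des, 1)
    if (length(z$times)) {
      expect_lt(max(abs(colSums(z$z / pi[z$idx]))), 1e-10)
    }
  }
})

test_that("single-cause influence reduces to the Nelson-Aalen residual form", {
  n <- 10
  d <- random_fixture(n, n_causes = 1, seed = 30)
  des <- design_full(d)
  z <- influence_matrix(d, des, 1)
  cp <- counting_processes(d, des, 1)
  # classical form: z_i(t) = sum_{u <= t} [dN_i(u) - Y_i(u) dLambda(u)] / Y(u)
  ue <- z$times
  for (i in seq_len(n)) {
    zi_expect <- vapply(ue, function(t) {
      ev <- sort(unique(d$time[d$cause == 1 & d$time <= t]))
      sum(vapply(ev, function(u) {
        Yu <- sum(d$time >= u)
        dLam <- sum(d$time == u & d$cause == 1) / Yu
        ((d$time[i] == u && d$cause[i] == 1) - (d$time[i] >= u) * dLam) / Yu
      }, 0))
    }, 0)
    expect_equal(unname(z$z[match(i, z$idx), ]), zi_expect, tolerance = 1e-12)
  }
})

test_that("phase-II Horvitz-Thompson variance is exact by enumeration (SRSWOR 2 of 4)", {
  z_vals <- c(0.3, -0.1, 0.2, -0.4)
  N <- 4
  n <- 2
  pi <- rep(n / N, N)
  pij <- n * (n - 1) / (N * (N - 1))
  pairs <- utils::combn(N, 2)
  totals <- vars <- numeric(ncol(pairs))
  d <- fixture4()
  for (s in seq_len(ncol(pairs))) {
    sel <- pairs[, s]
    xi <- integer(N)
    xi[sel] <- 1L
    P <- matrix(pij, N, N)
    diag(P) <- pi
    des <- design_custom(d, xi = xi, pi = pi, pairwise = P)
    zobj <- structure(
      list(
        times = 1, z = matrix(z_vals[sel], ncol = 1),
        idx = sel, cause = 1
      ),
      class = "influence_matrix"
    )
    totals[s] <- sum(z_vals[sel] / pi[sel])
    vars[s] <- suppressWarnings(phase2_variance(zobj, des))
  }
  true_var <- mean((totals - sum(z_vals))^2) # all 6 samples equally likely
  expect_equal(mean(vars), true_var, tolerance = 1e-12)
})

test_that("phase-II variance vanishes under a census and scales quadratically", {
  n <- 10
  d <- random_fixture(n, seed = 31)
  des <- design_full(d)
  z <- influence_matrix(d, des, 1)
  expect_true(all(phase2_variance(z, des) == 0))
  # quadratic scaling under an actual subsample
  des2 <- design_custom(d, xi = rep(1, n), pi = rep(0.5, n))
  z2 <- influence_matrix(d, des2, 1)
  v1 <- phase2_variance(z2, des2)
  z2$z <- 2 * z2$z
  expect_equal(phase2_variance(z2, des2), 4 * v1)
})

test_that("phase-I variance is the weighted sum of squared influences", {
  d <- fixture4()
  des <- design_full(d)
  zobj <- structure(
    list(times = 1, z = matrix(c(0.2, 0, 0, 0), ncol = 1), idx = 1:4, cause = 1),
    class = "influence_matrix"
  )
  expect_equal(phase1_variance(zobj, des), 0.04)
  zobj$z[] <- 0
  expect_equal(phase1_variance(zobj, des), 0)
})

test_that("phase-I variance tracks the empirical full-cohort variability", {
  B <- 400
  N <- 150
  sc <- sim_scenario("full", N = N, B = 1, seed = 1)
  lam <- s2 <- numeric(B)
  for (b in seq_len(B)) {
    set.seed(7000 + b)
    cohort <- generate_cohort(sc)
    des <- design_full(cohort)
    z <- influence_matrix(cohort, des, 1)
    if (!length(z$times)) next
    lam[b] <- sum(twophaseCIF:::tp_curves(
      twophaseCIF:::tp_prepare(cohort, des), 1
    )$dLstar)
    s2[b] <- phase1_variance(z, des)[length(z$times)]
  }
  expect_equal(mean(s2), stats::var(lam), tolerance = 0.2)
})

test_that("variance and intervals transform the hazard-scale uncertainty correctly", {
  expect_equal(variance_of_F(0, 0.01), 0.01)
  expect_equal(variance_of_F(1, 5), 0)
  expect_equal(variance_of_F(0.5, 0.04), 0.01)
  # degenerate interval at sigma = 0
  ci0 <- confidence_interval(0.3, 0)
  expect_equal(c(ci0$conf_low, ci0$conf_high), c(0.3, 0.3))
  # plug-in value with the standard-normal quantile
  ci <- confidence_interval(0.5, sigma = 0.2, alpha = 0.05)
  q <- qnorm(0.975)
  expect_equal(ci$conf_low, 0.5 * exp(-q * (1 - 0.5) / 0.5 * 0.2))
  expect_equal(ci$conf_high, 0.5 * exp(q * (1 - 0.5) / 0.5 * 0.2))
  # undefined at F = 0, clipped to [0, 1], monotone in alpha
  ci_zero <- confidence_interval(c(0, 0.5), c(0.1, 0.1))
  expect_true(is.na(ci_zero$conf_low[1]) && is.na(ci_zero$conf_high[1]))
  wide <- confidence_interval(0.2, 0.05, alpha = 0.05)
  narrow <- confidence_interval(0.2, 0.05, alpha = 0.10)
  expect_lt(wide$conf_low, narrow$conf_low)
  expect_gt(wide$conf_high, narrow$conf_high)
  expect_error(confidence_interval(0.5, 0.1, alpha = 1.2), "alpha")
})

test_that("the phase decomposition behaves as the sampling fraction grows", {
  n <- 30
  d <- random_fixture(n, seed = 40)
  fit_var <- function(p) {
    des <- design_custom(d, xi = rep(1, n), pi = rep(p, n))
    z <- influence_matrix(d, des, 1)
    tail <- length(z$times)
    c(
      phase1 = phase1_variance(z, des)[tail],
      phase2 = suppressWarnings(phase2_variance(z, des))[tail]
    )
  }
  v_mid <- fit_var(0.5)
  v_near <- fit_var(0.999)
  expect_gte(v_mid["phase2"], 0)
  # phase-II contribution dies off as pi -> 1
  expect_lt(v_near["phase2"], v_mid["phase2"] / 10)
})
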