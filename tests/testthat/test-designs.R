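test_that("simple random sampling carries SRSWOR inclusion probabilities", {
  d <- random_fixture(20, seed = 1)
  des <- sample_random(d, n = 5, seed = 7)
  expect_equal(sum(des$xi), 5)
  expect_equal(des$pi, rep(5 / 20, 20))
  sel <- which(des$xi == 1)
  expect_equal(
    pairwise_probability(des, sel[1], sel[2]),
    5 * 4 / (20 * 19)
  )
  expect_equal(pairwise_probability(des, sel[1], sel[1]), 0.25)
  # census: everyone in with probability one
  census <- sample_random(d, n = 20, seed = 1)
  expect_true(all(census$xi == 1) && all(census$pi == 1))
  expect_equal(pairwise_probability(census, 1, 2), 1)
  expect_error(sample_random(d, 21), "invalid design")
})

test_that("stratified sampling: probabilities, capping and one-stratum reduction", {
  d <- random_fixture(40, seed = 2)
  d$s <- rep(c("a", "b"), each = 20)
  des <- sample_stratified(d, "s", n_per_stratum = c(a = 15, b = 5), seed = 3)
  expect_equal(des$pi[1:20], rep(0.75, 20)) # 15/20, like 21/28 = 75% sampling
  expect_equal(des$pi[21:40], rep(0.25, 20))
  expect_equal(sum(des$xi[1:20]), 15)
  # capped quota takes the whole stratum with a warning
  expect_warning(
    cap <- sample_stratified(d, "s", n_per_stratum = c(a = 25, b = 5), seed = 3),
    "capped"
  )
  expect_true(all(cap$pi[1:20] == 1) && all(cap$xi[1:20] == 1))
  # single stratum degenerates to simple random sampling
  one <- sample_stratified(d, rep("all", 40), n_per_stratum = 10, seed = 5)
  sel <- which(one$xi == 1)
  expect_equal(one$pi, rep(0.25, 40))
  expect_equal(
    pairwise_probability(one, sel[1], sel[2]),
    10 * 9 / (40 * 39)
  )
  expect_error(sample_stratified(d, "s", n_per_stratum = 0), "quota")
})

test_that("stratified joint inclusion matches exhaustive enumeration (2 strata of 4)", {
  # two strata of 4 subjects, 2 sampled from each: enumerate all C(4,2)^2
  # equally likely selections and count joint inclusions.
  d <- random_fixture(8, seed = 4)
  strat <- rep(c("u", "v"), each = 4)
  pairs_u <- utils::combn(1:4, 2)
  pairs_v <- utils::combn(5:8, 2)
  joint <- matrix(0, 8, 8)
  nsel <- ncol(pairs_u) * ncol(pairs_v)
  for (a in seq_len(ncol(pairs_u))) {
    for (b in seq_len(ncol(pairs_v))) {
      s <- c(pairs_u[, a], pairs_v[, b])
      joint[s, s] <- joint[s, s] + 1
    }
  }
  joint <- joint / nsel
  des <- sample_stratified(d, strat, n_per_stratum = 2, seed = 1)
  # formula values: within stratum 2*1/(4*3) = 1/6; across 0.5*0.5 = 0.25
  expect_equal(joint[1, 2], 1 / 6)
  expect_equal(joint[1, 5], 0.25)
  sel <- which(des$xi == 1)
  for (i in sel) {
    for (j in sel) {
      expect_equal(pairwise_probability(des, i, j), joint[i, j],
        tolerance = 1e-12,
        label = paste("pi_", i, j)
      )
    }
  }
})

test_that("case-control sampling is balanced two-stratum SRSWOR", {
  d <- random_fixture(1000, seed = 5, p_censor = 0)
  case <- d$cause == 1
  n_case <- sum(case)
  des <- sample_case_control(d, case, n = 100, seed = 6)
  expect_equal(sum(des$xi[case]), 50)
  expect_equal(sum(des$xi[!case]), 50)
  expect_equal(unique(des$pi[case]), 50 / n_case)
  expect_equal(unique(des$pi[!case]), 50 / (1000 - n_case))
  expect_error(sample_case_control(d, rep(TRUE, 1000), 100), "invalid design")
  expect_error(sample_case_control(d, case, 99), "even")
})

test_that("phase-II sample of the default truth holds exactly n/2 cases", {
  sc <- sim_scenario("case_control", n = 100, seed = 11)
  cohort <- generate_cohort(sc, seed = 21)
  des <- sample_case_control(cohort, cohort$case == 1L, n = 100, seed = 31)
  expect_equal(sum(cohort$case[des$xi == 1]), 50)
})

test_that("nested case-control: Samuelsen weights on the 3-subject example", {
  d <- data.frame(time = c(1, 2, 3), cause = c(1L, 0L, 0L))
  des <- sample_ncc(d, cause = 1, m = 1, seed = 1)
  expect_equal(des$pi[1], 1) # the case
  expect_equal(des$pi[2:3], c(0.5, 0.5)) # 1 - (1 - 1/2)
  expect_equal(sum(des$xi), 2) # case + one control
  # m at least the pool size: every subject at risk at a case time gets pi = 1
  big <- sample_ncc(d, cause = 1, m = 5, seed = 1)
  expect_equal(big$pi, c(1, 1, 1))
  expect_equal(sum(big$xi), 3)
  expect_error(sample_ncc(d, cause = 2, m = 1), "no event")
})

test_that("nested case-control inclusion probabilities match their Monte-Carlo frequencies", {
  set.seed(9)
  N <- 25
  d <- data.frame(
    time = round(runif(N, 0.2, 4), 2),
    cause = sample(c(0L, 1L, 2L), N, TRUE, prob = c(.3, .4, .3))
  )
  R <- 1500
  joint <- matrix(0, N, N)
  for (r in seq_len(R)) {
    des_r <- sample_ncc(d, 1, m = 2, seed = 5000 + r)
    s <- which(des_r$xi == 1)
    joint[s, s] <- joint[s, s] + 1
  }
  emp <- joint / R
  des <- sample_ncc(d, 1, m = 2, seed = 1)
  P <- twophaseCIF:::pairwise_matrix(des, seq_len(N))
  mc_se <- sqrt(pmax(P * (1 - P), 1e-9) / R)
  expect_lt(max(abs(diag(emp) - des$pi) / (3 * sqrt(des$pi * (1 - des$pi) / R + 1e-9))), 1.5)
  expect_lt(max(abs(P - emp) / (3 * mc_se + 1e-9)), 1.5)
})

test_that("every design is Horvitz-Thompson unbiased for cohort totals", {
  sc <- sim_scenario("random", N = 60, n = 20, seed = 1)
  cohort <- generate_cohort(sc, seed = 99)
  a1 <- rep(1, 60)
  a2 <- as.numeric(cohort$cause == 1) # N_i1(2): cause-1 event by horizon
  draws <- list(
    random = function(s) sample_random(cohort, 20, seed = s),
    cc = function(s) sample_case_control(cohort, cohort$case == 1L, 20, seed = s),
    strat = function(s) {
      sample_stratified(cohort, ifelse(cohort$case == 1, "e", "o"),
        n_per_stratum = 10, seed = s
      )
    },
    ncc = function(s) sample_ncc(cohort, 1, m = 1, seed = s)
  )
  R <- 400
  for (nm in names(draws)) {
    ht1 <- ht2 <- sz <- numeric(R)
    expected_sz <- NULL
    for (r in seq_len(R)) {
      des <- suppressWarnings(draws[[nm]](10000 + r))
      sel <- des$xi == 1
      ht1[r] <- sum(a1[sel] / des$pi[sel])
      ht2[r] <- sum(a2[sel] / des$pi[sel])
      sz[r] <- sum(des$xi)
      if (r == 1) expected_sz <- sum(des$pi)
    }
    expect_lt(abs(mean(ht1) - 60) / (stats::sd(ht1) / sqrt(R) + 1e-9), 4)
    expect_lt(abs(mean(ht2) - sum(a2)) / (stats::sd(ht2) / sqrt(R) + 1e-9), 4)
    # E[phase-II size] = sum of inclusion probabilities
    expect_lt(abs(mean(sz) - expected_sz) / (stats::sd(sz) / sqrt(R) + 1e-9), 4)
  }
})

test_that("custom designs validate and pass through pairwise tables", {
  d <- fixture4()
  P <- matrix(0.25, 4, 4)
  diag(P) <- 0.5
  des <- design_custom(d, xi = rep(1, 4), pi = rep(0.5, 4), pairwise = P)
  expect_equal(pairwise_probability(des, 1, 2), 0.25)
  expect_equal(pairwise_probability(des, 2, 2), 0.5)
  Pbad <- P
  Pbad[1, 2] <- 0.3
  expect_error(design_custom(d, rep(1, 4), rep(0.5, 4), pairwise = Pbad), "symmetric")
  des2 <- design_custom(d, xi = c(1, 1, 0, 1), pi = c(.5, .5, NA, .5))
  expect_error(pairwise_probability(des2, 1, 3), "unselected")
})
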