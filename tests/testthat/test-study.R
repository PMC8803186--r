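test_that("the Wald Monte Carlo interval reproduces standard bounds", {
  expect_equal(round(monte_carlo_ci(0.05, 10000), 3),
               c(lower = 0.046, upper = 0.054))
  expect_equal(round(monte_carlo_ci(0.05, 710), 3),
               c(lower = 0.034, upper = 0.066))
  expect_equal(round(100 * monte_carlo_ci(28853 / 37100, 37100), 2),
               c(lower = 77.35, upper = 78.19))
  expect_equal(monte_carlo_ci(0, 50), c(lower = 0, upper = 0))
  expect_equal(monte_carlo_ci(1, 50), c(lower = 1, upper = 1))
})

test_that("replicate evaluation is consistent across strategies", {
  scn <- new_scenario("lognormal", -5, 1, 1)  # deep below threshold: no censoring
  r <- simulate_replicate(scn, seed = 21)
  res <- evaluate_replicate(r, methods = c("bfd", "mc", "co", "cna"))
  expect_false(any(res$has_uncertain))
  expect_equal(res$censoring_pattern, rep("none", 4))
  expect_equal(length(unique(res$reject)), 1L)  # identical decisions

  # strong effect pushing group 2 over the cutoff
  scn2 <- new_scenario("lognormal", 10, 25, 1)
  r2 <- simulate_replicate(scn2, seed = 22)
  expect_true(all(r2$normalized$phi[r2$normalized$group == 2] == 0))
  res2 <- evaluate_replicate(r2, methods = c("ctot", "mc", "co", "cna"))
  expect_true(res2$not_analyzed[res2$method == "cna"])
  expect_false(res2$reject[res2$method == "cna"])
  expect_true(res2$degenerate[res2$method == "co"])  # < 2 complete in group 2
  expect_false(res2$reject[res2$method == "co"])
  expect_false(res2$degenerate[res2$method == "ctot"])
})

test_that("decision accounting sums to the number of replicates", {
  set.seed(151)
  scn <- new_scenario("lognormal", 12, 6, 2)
  methods <- c("bfd", "ctot", "mc", "co", "cna")
  tally <- stats::setNames(rep(0, length(methods)), methods)
  n_rep <- 0
  for (i in 1:50) {
    r <- simulate_replicate(scn)
    res <- evaluate_replicate(r, methods = methods)
    if (!any(res$has_uncertain)) next
    n_rep <- n_rep + 1
    # reject / non-reject partition: every row is exactly one of the two
    expect_true(all(res$reject + (!res$reject) == 1))
    # degenerate and not-analyzed records never count as rejections
    expect_true(all(!(res$reject & (res$degenerate | res$not_analyzed))))
    tally <- tally + res$reject
  }
  expect_true(all(tally <= n_rep))
})

test_that("alpha = 1 rejects every analyzable comparison and reps = 0 is flagged", {
  s <- run_power_study(families = "lognormal", n_scenarios = 2,
                       reps_per_scenario = 30, alpha = 1, seed = 31,
                       methods = c("bfd", "ctot", "mc"))
  r <- tidy(s)
  # every non-degenerate analyzable comparison is rejected at alpha = 1
  expect_true(all(r$correct + r$degenerate + r$not_analyzed == r$n_rep))
  s0 <- run_power_study(families = "lognormal", n_scenarios = 2,
                        reps_per_scenario = 0, seed = 31, methods = "ctot")
  r0 <- tidy(s0)
  expect_equal(r0$n_rep, 0L)
  expect_true(is.na(r0$power))
})

test_that("study reports are bit-identical under a fixed seed", {
  cfg <- list(families = "weibull", n_scenarios = 2, reps_per_scenario = 40,
              seed = 99, methods = c("ctot", "co"))
  s1 <- do.call(run_power_study, cfg)
  s2 <- do.call(run_power_study, cfg)
  expect_identical(s1$results, s2$results)
  t1 <- run_type1_study(reps = 100, seed = 5, methods = "ctot")
  t2 <- run_type1_study(reps = 100, seed = 5, methods = "ctot")
  expect_identical(t1$results, t2$results)
  expect_identical(t1$pooled_uncertain, t2$pooled_uncertain)
})

test_that("type-I scenarios must be null and alpha = 0 never rejects", {
  bad <- type1_scenarios()
  bad$beta1[2] <- 1
  expect_error(run_type1_study(scenarios = bad, reps = 10, seed = 1),
               "beta1 = 0")
  s <- run_type1_study(reps = 200, alpha = 0, seed = 13, methods = c("ctot", "mc"))
  expect_true(all(tidy(s)$rejections == 0))
})

test_that("empirical power is non-decreasing in |beta1| (within 2 MC SEs)", {
  set.seed(163)
  reps <- 250
  power_at <- function(b1) {
    scn <- new_scenario("lognormal", 10, b1, 1)
    rej <- 0
    for (i in seq_len(reps)) {
      r <- simulate_replicate(scn)
      res <- evaluate_replicate(r, methods = "ctot")
      rej <- rej + res$reject
    }
    rej / reps
  }
  p <- vapply(c(0.5, 3, 6), power_at, numeric(1))
  se <- sqrt(pmax(p * (1 - p), 0.25 / reps) / reps)
  expect_true(all(diff(p) >= -2 * (se[-1] + se[-3])))
})

test_that("analytic t-test power matches its boundary cases and a simulation", {
  expect_equal(t_test_power(10, 10, 1, 5), 0.05)
  expect_gt(t_test_power(20, 32, 1, 5), 0.9999)  # 12-SD effect saturates
  # reference check against the standard power routine
  expect_equal(t_test_power(0, 2, 1, 5),
               stats::power.t.test(n = 5, delta = 2, sd = 1, strict = TRUE)$power,
               tolerance = 1e-10)
  # simulation oracle
  set.seed(173)
  B <- 2e4
  rej <- 0
  for (b in seq_len(B)) {
    x <- rnorm(5, 0); y <- rnorm(5, 2)
    vx <- var(x); vy <- var(y)
    sp2 <- (4 * vx + 4 * vy) / 8
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 5))
    rej <- rej + (abs(tstat) > qt(0.975, 8))
  }
  p_hat <- rej / B
  p_true <- t_test_power(0, 2, 1, 5)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / B))
})
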