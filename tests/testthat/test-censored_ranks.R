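# the worked example used throughout: group 1 events {1, 3};
# group 2 event {2} and one observation censored at 4
example_data <- function() new_normalized(c(1, 3), c(2, 4), phi2 = c(1, 0))

test_that("risk table counts and hypergeometric moments match hand enumeration", {
  rt <- build_risk_table(example_data())
  expect_equal(rt$d, c(1, 2, 3))
  expect_equal(rt$p_d, c(4, 3, 2))
  expect_equal(rt$p_d1, c(2, 1, 1))
  expect_equal(rt$o_d, c(1, 1, 1))
  expect_equal(rt$o_d1, c(1, 0, 1))
  expect_equal(rt$e_d1, c(0.5, 1 / 3, 0.5))
  expect_equal(rt$v_d1, c(0.25, 2 / 9, 0.25))
  # structural invariants
  expect_equal(rt$p_d, rt$p_d1 + rt$p_d2)
  expect_equal(rt$o_d, rt$o_d1 + rt$o_d2)
  expect_equal((rt$o_d1 - rt$e_d1) + (rt$o_d2 - (rt$o_d - rt$e_d1)), rep(0, 3))
})

test_that("symmetric risk sets give symmetric expectations; no events give an empty table", {
  d <- new_normalized(1:5, 1:5)  # p_d1 = p_d2 at the first point
  rt <- build_risk_table(d)
  expect_equal(rt$e_d1[1], rt$o_d[1] / 2)
  all_cens <- new_normalized(c(1, 2), c(3, 4), phi1 = c(0, 0), phi2 = c(0, 0))
  expect_equal(nrow(build_risk_table(all_cens)), 0L)
})

test_that("moments agree with survival::survdiff and brute-force hypergeometric sums", {
  skip_if_not_installed("survival")
  set.seed(3)
  for (i in 1:25) {
    d <- random_normalized()
    rt <- build_risk_table(d)
    ls <- linear_statistic(km_left_limits(rt) %>% fh_weights(0, 0))
    sd_ <- survival::survdiff(
      survival::Surv(d$delta_y, d$phi) ~ d$group)
    expect_equal(ls$u, unname(sd_$obs[1] - sd_$exp[1]), tolerance = 1e-9)
    expect_equal(ls$v, unname(sd_$var[1, 1]), tolerance = 1e-9)
    for (j in seq_len(nrow(rt))) {
      bm <- hyper_moments_brute(rt$p_d1[j], rt$p_d2[j], rt$o_d[j])
      expect_equal(rt$e_d1[j], bm$mean, tolerance = 1e-12)
      expect_equal(rt$v_d1[j], bm$var, tolerance = 1e-12)
    }
  }
})

test_that("Kaplan-Meier left limits follow the product-limit recursion", {
  rt <- km_left_limits(build_risk_table(example_data()))
  expect_equal(rt$s_minus, c(1, 0.75, 0.5))
  one <- km_left_limits(build_risk_table(new_normalized(3, c(4, 5), phi2 = c(0, 0))))
  expect_equal(one$s_minus, 1)
  # no censoring, distinct values: left limits step down by 1/n
  n <- 6
  rt2 <- km_left_limits(build_risk_table(new_normalized(1:3, 4:6)))
  expect_equal(rt2$s_minus, 1 - (0:(n - 1)) / n)
})

test_that("Fleming-Harrington weights cover the unit, early and late regimes", {
  rt <- km_left_limits(build_risk_table(example_data()))
  expect_equal(fh_weights(rt, 0, 0)$w_d, rep(1, 3))       # plain log-rank
  expect_equal(fh_weights(rt, 1, 0)$w_d, c(1, 0.75, 0.5)) # early emphasis
  expect_equal(fh_weights(rt, 0, 1)$w_d[1], 0)            # first point: 1 - S = 0
  expect_equal(fh_weights(rt, 0, 0)$w_d[1], 1)            # 0^0 convention
  expect_error(fh_weights(rt, -1, 0), "nonnegative")
})

test_that("the linear statistic matches the hand sum and its symmetries", {
  rt <- fh_weights(km_left_limits(build_risk_table(example_data())), 0, 0)
  ls <- linear_statistic(rt)
  expect_equal(ls$u, 2 / 3)
  expect_equal(ls$v, 0.25 + 2 / 9 + 0.25)
  # mirror-image groups: u = 0
  m <- new_normalized(c(1, 2, 3), c(1, 2, 3))
  lm_ <- linear_statistic(fh_weights(km_left_limits(build_risk_table(m)), 0, 0))
  expect_equal(lm_$u, 0)
  empty <- build_risk_table(new_normalized(1, 2, phi1 = 0, phi2 = 0))
  expect_equal(linear_statistic(empty), list(u = 0, v = 0))
})

test_that("scores reproduce the statistic and reduce to classic log-rank scores", {
  d <- example_data()
  rt <- fh_weights(km_left_limits(build_risk_table(d)), 0, 0)
  sc <- logrank_scores(d, rt)
  expect_equal(sum(sc[d$group == 1]), linear_statistic(rt)$u, tolerance = 1e-12)
  # no censoring, no ties: c_i = phi_i - cumulative hazard at y_i
  d2 <- new_normalized(c(2, 5, 9), c(1, 7, 11))
  rt2 <- fh_weights(km_left_limits(build_risk_table(d2)), 0, 0)
  sc2 <- logrank_scores(d2, rt2)
  lambda <- cumsum(rt2$o_d / rt2$p_d)
  expect_equal(sc2, 1 - lambda[match(d2$delta_y, rt2$d)])
  # censored below the first detection point scores zero
  d3 <- new_normalized(c(5, 6), c(1, 7), phi2 = c(0, 1))
  rt3 <- fh_weights(km_left_limits(build_risk_table(d3)), 0, 0)
  expect_equal(logrank_scores(d3, rt3)[3], 0)
})

test_that("score-sum identity holds across random data and all weight settings", {
  set.seed(19)
  for (i in 1:20) {
    d <- random_normalized()
    for (p in c(0, 0.5, 1)) for (q in c(0, 0.5, 1)) {
      rt <- fh_weights(km_left_limits(build_risk_table(d)), p, q)
      expect_equal(sum(logrank_scores(d, rt)[d$group == 1]),
                   linear_statistic(rt)$u, tolerance = 1e-10)
    }
  }
})

test_that("exact permutation p-values enumerate the subset-sum distribution", {
  # 6 subsets of {1.5, .5, -.5, -1.5}: sums {2, 1, 0, 0, -1, -2}
  expect_equal(exact_permutation_pvalue(c(1.5, 0.5, -0.5, -1.5), 2), 1 / 3)
  expect_equal(exact_permutation_pvalue(rep(2, 6), 3), 1)
  # n = 10, n1 = 5: denominator 252
  set.seed(5)
  p <- exact_permutation_pvalue(rnorm(10), 5)
  expect_equal(p * 252, round(p * 252), tolerance = 1e-9)
  expect_gt(p, 0)
  expect_error(exact_permutation_pvalue(rnorm(30), 15), "enumeration limit")
})

test_that("Monte Carlo p-values converge on the exact value and are seed-stable", {
  sc <- c(1.5, 0.5, -0.5, -1.5)
  p_mc <- montecarlo_permutation_pvalue(sc, 2, B = 1e5, seed = 9)
  se <- sqrt((1 / 3) * (2 / 3) / 1e5)
  expect_lt(abs(p_mc - 1 / 3), 3 * se)
  expect_equal(montecarlo_permutation_pvalue(sc, 2, B = 5000, seed = 4),
               montecarlo_permutation_pvalue(sc, 2, B = 5000, seed = 4))
  p_a <- montecarlo_permutation_pvalue(sc, 2, B = 2e4, seed = 1)
  p_b <- montecarlo_permutation_pvalue(sc, 2, B = 2e4, seed = 2)
  expect_lt(abs(p_a - p_b), 4 * sqrt((1 / 3) * (2 / 3) / 2e4))
  expect_equal(montecarlo_permutation_pvalue(rep(1, 5), 2, B = 1000, seed = 3), 1)
})

test_that("normal-approximation p-values follow the standard normal reference", {
  expect_equal(asymptotic_pvalue(0, 1), 1)
  v <- 1
  u <- 1.959964
  expect_equal(asymptotic_pvalue(u, v), 0.05, tolerance = 1e-6)
  expect_equal(asymptotic_pvalue(2 / 3, 0.25 + 2 / 9 + 0.25), 0.4328, tolerance = 1e-4)
  expect_equal(asymptotic_pvalue(1, 0), 1)  # degenerate variance
})

test_that("ctot_test equals the per-labeling oracle on censoring-free data", {
  set.seed(23)
  for (i in 1:10) {
    d <- random_normalized(censor_prob = 0)
    fit <- ctot_test(d, pvalue_mode = "exact")
    expect_equal(fit$p_value,
                 oracle_exact_pvalue(d$delta_y, d$phi, attr(d, "n1")),
                 tolerance = 1e-10)
  }
})

test_that("the test is invariant under strictly increasing transforms", {
  set.seed(31)
  for (i in 1:10) {
    d <- random_normalized()
    fit <- ctot_test(d, pvalue_mode = "exact")
    d2 <- d
    d2$delta_y <- exp(d$delta_y / 4)  # order-preserving, censoring fixed
    fit2 <- ctot_test(d2, pvalue_mode = "exact")
    expect_equal(fit$p_value, fit2$p_value, tolerance = 1e-12)
  }
})

test_that("fully censored data degenerates to p = 1 with a reason", {
  d <- new_normalized(c(1, 2), c(3, 4), phi1 = c(0, 0), phi2 = c(0, 0))
  fit <- ctot_test(d)
  expect_equal(fit$p_value, 1)
  expect_equal(fit$z, 0)
  expect_match(fit$degenerate, "no detection points")
})

test_that("swapping group labels negates U and preserves the two-sided p", {
  set.seed(37)
  for (i in 1:10) {
    d <- random_normalized()
    swapped <- new_normalized(
      d$delta_y[d$group == 2], d$delta_y[d$group == 1],
      d$phi[d$group == 2], d$phi[d$group == 1]
    )
    f1 <- ctot_test(d, pvalue_mode = "exact")
    f2 <- ctot_test(swapped, pvalue_mode = "exact")
    expect_equal(f1$statistic_u, -f2$statistic_u, tolerance = 1e-12)
    expect_equal(f1$p_value, f2$p_value, tolerance = 1e-12)
  }
})

test_that("the exact test is valid: P(p <= alpha) <= alpha under relabeling", {
  set.seed(41)
  for (i in 1:5) {
    d <- random_normalized(n1 = 4, n2 = 4)
    rt <- fh_weights(km_left_limits(build_risk_table(d)), 0, 0)
    sc <- logrank_scores(d, rt)
    n <- length(sc)
    n1 <- attr(d, "n1")
    labelings <- utils::combn(n, n1)
    pvals <- apply(labelings, 2, function(ix) {
      reord <- c(sc[ix], sc[-ix])
      exact_permutation_pvalue(reord, n1)
    })
    for (alpha in c(0.01, 0.05, 0.1, 0.25, 0.5, 1)) {
      expect_lte(mean(pvals <= alpha), alpha + 1e-12)
    }
  }
})

test_that("tidy and glance expose the fit as tibbles", {
  fit <- ctot_test(example_data())
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$p_value, fit$p_value)
  gl <- glance(fit)
  expect_equal(gl$n_censored, 1L)
  expect_equal(gl$n_detection_points, 3L)
})
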