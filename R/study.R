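# Monte Carlo power and type-I-error experiments comparing CTOT with the
# MC / CO / CNA strategies and the full-data benchmark BFD.

# per-scenario seeds derived from a master seed by a fixed affine counter
# scheme, kept below 2^31 so scenario subsets can be re-run independently
.derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(counter)) %% 2147483587)
}

# one replicate, raw vectors in, decision list out; shared by both studies
.eval_fast <- function(draw, alpha, methods, var_equal = FALSE) {
  g1 <- draw$group == 1L
  cens1 <- any(draw$phi[g1] == 0L)
  cens2 <- any(draw$phi[!g1] == 0L)
  out <- list(
    has_uncertain = cens1 || cens2,
    one_group = xor(cens1, cens2),
    reject = logical(0), degenerate = logical(0), not_analyzed = logical(0)
  )
  for (m in methods) {
    p <- NA_real_
    degen <- FALSE
    not_an <- FALSE
    if (m == "ctot") {
      fit <- .ctot_core(draw$value, draw$phi, draw$group)
      p <- fit$p_value
      degen <- !is.null(fit$degenerate)
    } else if (m == "bfd") {
      p <- .ttest_fast(draw$true_delta_y[g1], draw$true_delta_y[!g1], var_equal)
    } else if (m == "mc") {
      p <- .ttest_fast(draw$value[g1], draw$value[!g1], var_equal)
    } else if (m == "co") {
      keep <- draw$phi == 1L
      p <- .ttest_fast(draw$value[g1 & keep], draw$value[!g1 & keep], var_equal)
    } else if (m == "cna") {
      if (cens1 || cens2) {
        not_an <- TRUE
      } else {
        p <- .ttest_fast(draw$value[g1], draw$value[!g1], var_equal)
      }
    }
    if (!not_an && is.na(p)) {
      degen <- TRUE
      p <- 1
    }
    # degenerate and not-analyzed replicates always count as non-rejections
    out$reject[m] <- !not_an && !degen && p <= alpha
    out$degenerate[m] <- degen
    out$not_analyzed[m] <- not_an
  }
  out
}

#' Analyze one simulated replicate with several strategies
#'
#' Runs the requested methods on a [simulate_replicate()] object — CTOT with
#' the exact two-sided test, MC/CO/CNA via two-sample t-tests, BFD on the
#' retained uncensored truth — and records the decision at level `alpha`.
#' Degenerate comparisons (e.g. CO with fewer than 2 complete observations in
#' a group) are recorded as non-rejections, never raised; CNA targets with
#' censoring are recorded as "not analyzed" non-rejections.
#'
#' @param rep A `sim_replicate` object.
#' @param alpha Significance level (default 0.05).
#' @param methods Strategies to run.
#' @param var_equal t-test variant for the t-based strategies.
#' @return A tibble with one row per method: `method`, `reject`,
#'   `degenerate`, `not_analyzed`, plus the replicate-level flags
#'   `has_uncertain` and `censoring_pattern` (`"none"`, `"one_group"`,
#'   `"both_groups"`).
#' @export
evaluate_replicate <- function(rep, alpha = 0.05,
                               methods = c("bfd", "ctot", "mc", "co", "cna"),
                               var_equal = FALSE) {
  stopifnot(inherits(rep, "sim_replicate"))
  norm <- rep$normalized
  draw <- list(
    group = norm$group, phi = norm$phi, value = norm$delta_y,
    true_delta_y = c(rep$true_delta_y$group1, rep$true_delta_y$group2)
  )
  res <- .eval_fast(draw, alpha, methods, var_equal)
  pattern <- if (!res$has_uncertain) "none" else if (res$one_group) "one_group" else "both_groups"
  tibble::tibble(
    method = methods,
    reject = unname(res$reject[methods]),
    degenerate = unname(res$degenerate[methods]),
    not_analyzed = unname(res$not_analyzed[methods]),
    has_uncertain = res$has_uncertain,
    censoring_pattern = pattern
  )
}

# accumulate decisions for one scenario; returns per-method counts
.run_scenario <- function(scn, reps, alpha, methods, var_equal, seed,
                          keep_only_uncertain) {
  nm <- length(methods)
  correct_all <- correct_kept <- degen_kept <- notan_kept <- integer(nm)
  names(correct_all) <- names(correct_kept) <- names(degen_kept) <-
    names(notan_kept) <- methods
  n_kept <- 0L
  n_one_group <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(reps)) {
      draw <- .sim_draw(scn)
      res <- .eval_fast(draw, alpha, methods, var_equal)
      correct_all <- correct_all + res$reject[methods]
      if (res$has_uncertain) {
        n_kept <- n_kept + 1L
        n_one_group <- n_one_group + res$one_group
        correct_kept <- correct_kept + res$reject[methods]
        degen_kept <- degen_kept + res$degenerate[methods]
        notan_kept <- notan_kept + res$not_analyzed[methods]
      }
    }
  })
  list(correct_all = correct_all, correct_kept = correct_kept,
       degenerate_kept = degen_kept, not_analyzed_kept = notan_kept,
       n_kept = n_kept, n_one_group = n_one_group, n_total = reps)
}

#' Monte Carlo (Wald) confidence interval for an empirical proportion
#'
#' `p_hat +/- z * sqrt(p_hat (1 - p_hat) / n)`, truncated to `[0, 1]`.
#'
#' @param p_hat Empirical proportion.
#' @param n Number of replicates behind it.
#' @param z Normal quantile (default 1.96 for 95%).
#' @return Named numeric `c(lower, upper)`.
#' @export
#' @examples
#' monte_carlo_ci(0.05, 10000)  # c(0.0457, 0.0543)
monte_carlo_ci <- function(p_hat, n, z = 1.96) {
  stopifnot(p_hat >= 0, p_hat <= 1, n >= 1)
  half <- z * sqrt(p_hat * (1 - p_hat) / n)
  c(lower = max(0, p_hat - half), upper = min(1, p_hat + half))
}

#' Empirical power study over random scenarios
#'
#' For each family, draws `n_scenarios` random parameter sets
#' ([draw_power_scenarios()]), simulates `reps_per_scenario` replicates per
#' scenario, analyzes each replicate with every method, and pools decisions
#' over the replicates that contain at least one uncertain observation (at
#' least one Cq at or above `c1`). Every drawn effect is nonzero almost
#' surely, so a "correct decision" is a two-sided rejection at `alpha`,
#' regardless of direction. CNA not-analyzed and degenerate CO replicates
#' count as non-rejections and are tallied separately.
#'
#' @param families Simulation families to run.
#' @param n_scenarios Scenarios per family.
#' @param reps_per_scenario Replicates per scenario.
#' @param n_per_group Samples per group.
#' @param alpha Significance level.
#' @param c1 Maximum quality cycle.
#' @param seed Master seed; scenario seeds are derived deterministically.
#' @param methods Strategies to compare.
#' @param sigma_scheme Dispersion assignment across scenarios
#'   (see [draw_power_scenarios()]).
#' @param var_equal t-test variant used by the t-based strategies.
#' @return An object of class `ctot_power_study`: list with `results` (tibble:
#'   `family`, `method`, `n_total`, `n_rep`, `correct`, `power`, `ci_lower`,
#'   `ci_upper`, `degenerate`, `not_analyzed`, `pct_one_group_uncertain`) and
#'   `config`.
#' @export
run_power_study <- function(families = c("lognormal", "weibull", "loglogistic"),
                            n_scenarios = 100, reps_per_scenario = 1000,
                            n_per_group = 5, alpha = 0.05, c1 = 40, seed = 1L,
                            methods = c("bfd", "ctot", "mc", "co", "cna"),
                            sigma_scheme = "alternate", var_equal = FALSE) {
  families <- match.arg(families, .sim_families, several.ok = TRUE)
  results <- purrr::map_dfr(seq_along(families), function(fi) {
    fam <- families[fi]
    scen <- draw_power_scenarios(fam, n_scenarios, sigma_scheme = sigma_scheme,
                                 n_per_group = n_per_group, c1 = c1,
                                 seed = .derive_seed(seed, fi * 100000))
    acc <- NULL
    for (i in seq_len(nrow(scen))) {
      got <- .run_scenario(as.list(scen[i, ]), reps_per_scenario, alpha,
                           methods, var_equal,
                           .derive_seed(seed, fi * 100000 + i), TRUE)
      if (is.null(acc)) acc <- got
      else {
        for (f in c("correct_all", "correct_kept", "degenerate_kept",
                    "not_analyzed_kept", "n_kept", "n_one_group", "n_total")) {
          acc[[f]] <- acc[[f]] + got[[f]]
        }
      }
    }
    purrr::map_dfr(methods, function(m) {
      pw <- if (acc$n_kept > 0) acc$correct_kept[[m]] / acc$n_kept else NA_real_
      ci <- if (acc$n_kept > 0) monte_carlo_ci(pw, acc$n_kept) else c(NA_real_, NA_real_)
      tibble::tibble(
        family = fam, method = m,
        n_total = acc$n_total, n_rep = acc$n_kept,
        correct = acc$correct_kept[[m]], power = pw,
        ci_lower = ci[[1]], ci_upper = ci[[2]],
        degenerate = acc$degenerate_kept[[m]],
        not_analyzed = acc$not_analyzed_kept[[m]],
        pct_one_group_uncertain = if (acc$n_kept > 0) acc$n_one_group / acc$n_kept else NA_real_
      )
    })
  })
  structure(
    list(results = results,
         config = list(families = families, n_scenarios = n_scenarios,
                       reps_per_scenario = reps_per_scenario,
                       n_per_group = n_per_group, alpha = alpha, c1 = c1,
                       seed = seed, methods = methods,
                       sigma_scheme = sigma_scheme, var_equal = var_equal,
                       t_test = if (var_equal) "pooled" else "welch")),
    class = "ctot_power_study"
  )
}

#' Empirical type-I-error study under the null
#'
#' Simulates `reps` replicates for each null scenario (by default the four
#' log-normal parameter sets with `beta1 = 0`, `beta0` in {5, 10}, `sigma` in
#' {1, 2}) and reports every method's rejection rate at `alpha` over *all*
#' replicates, plus the pooled CTOT rejection rate restricted to replicates
#' with at least one uncertain observation, each with its Monte Carlo 95% CI.
#'
#' @param scenarios Null scenario tibble (default [type1_scenarios()]); every
#'   `beta1` must be 0.
#' @param reps Replicates per scenario (default 10000).
#' @inheritParams run_power_study
#' @return An object of class `ctot_type1_study`: list with `results`
#'   (tibble: `scenario_id`, `beta0`, `sigma`, `method`, `n`, `rejections`,
#'   `rate`, `ci_lower`, `ci_upper`), `pooled_uncertain` (list: `method`,
#'   `n_rep`, `rejections`, `rate`, `ci`), and `config`.
#' @export
run_type1_study <- function(scenarios = type1_scenarios(), reps = 10000,
                            alpha = 0.05, c1 = 40, seed = 1L,
                            methods = c("bfd", "ctot", "mc", "co"),
                            var_equal = FALSE) {
  if (any(scenarios$beta1 != 0)) {
    stop("type-I-error scenarios must all have beta1 = 0", call. = FALSE)
  }
  scenarios$c1 <- c1
  kept_total <- 0L
  kept_ctot_rej <- 0L
  results <- purrr::map_dfr(seq_len(nrow(scenarios)), function(i) {
    acc <- .run_scenario(as.list(scenarios[i, ]), reps, alpha, methods,
                         var_equal, .derive_seed(seed, i), FALSE)
    if ("ctot" %in% methods) {
      kept_total <<- kept_total + acc$n_kept
      kept_ctot_rej <<- kept_ctot_rej + acc$correct_kept[["ctot"]]
    }
    purrr::map_dfr(methods, function(m) {
      rate <- acc$correct_all[[m]] / reps
      ci <- monte_carlo_ci(rate, reps)
      tibble::tibble(
        scenario_id = scenarios$scenario_id[i],
        beta0 = scenarios$beta0[i], sigma = scenarios$sigma[i],
        method = m, n = reps, rejections = acc$correct_all[[m]],
        rate = rate, ci_lower = ci[[1]], ci_upper = ci[[2]]
      )
    })
  })
  pooled <- NULL
  if ("ctot" %in% methods) {
    rate <- if (kept_total > 0) kept_ctot_rej / kept_total else NA_real_
    pooled <- list(method = "ctot", n_rep = kept_total,
                   rejections = kept_ctot_rej, rate = rate,
                   ci = if (kept_total > 0) monte_carlo_ci(rate, kept_total)
                        else c(lower = NA_real_, upper = NA_real_))
  }
  structure(
    list(results = results, pooled_uncertain = pooled,
         config = list(reps = reps, alpha = alpha, c1 = c1, seed = seed,
                       methods = methods, var_equal = var_equal,
                       t_test = if (var_equal) "pooled" else "welch")),
    class = "ctot_type1_study"
  )
}

#' Analytic power of the two-sided two-sample t-test
#'
#' Noncentral-t power with `df = 2n - 2` and noncentrality
#' `|mu1 - mu2| sqrt(n/2) / sd` for equal group sizes `n`.
#'
#' @param mu1,mu2 Group means.
#' @param sd Common standard deviation (> 0).
#' @param n_per_group Samples per group (>= 2).
#' @param alpha Significance level.
#' @return Power in `[0, 1]`.
#' @export
#' @examples
#' t_test_power(0, 2, 1, 5)  # moderate effect at n = 5
t_test_power <- function(mu1, mu2, sd, n_per_group, alpha = 0.05) {
  stopifnot(sd > 0, n_per_group >= 2)
  df <- 2 * n_per_group - 2
  ncp <- abs(mu1 - mu2) * sqrt(n_per_group / 2) / sd
  crit <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(crit, df, ncp = ncp) + stats::pt(-crit, df, ncp = ncp)
}

#' @export
print.ctot_power_study <- function(x, ...) {
  cat("Empirical power study (", x$config$n_scenarios, " scenarios x ",
      x$config$reps_per_scenario, " replicates per family; pooled over ",
      "replicates with uncertain observations)\n", sep = "")
  print(x$results)
  invisible(x)
}

#' @export
print.ctot_type1_study <- function(x, ...) {
  cat("Empirical type-I-error study (", x$config$reps,
      " replicates per null scenario, alpha = ", x$config$alpha, ")\n", sep = "")
  print(x$results)
  if (!is.null(x$pooled_uncertain)) {
    p <- x$pooled_uncertain
    cat(sprintf("Pooled CTOT rate on the %d replicates with uncertain observations: %.4f (%.4f-%.4f)\n",
                p$n_rep, p$rate, p$ci[[1]], p$ci[[2]]))
  }
  invisible(x)
}
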