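# Core machinery of the cycle-to-threshold (CTOT) test: risk-set tabulation at
# each distinct detection point, hypergeometric moments, Fleming-Harrington
# weights from the pooled Kaplan-Meier left limit, the weighted
# observed-minus-expected statistic, and its exact permutation distribution.

.ctot_cache <- new.env(parent = emptyenv())

# cached choose(n, n1) column-index matrix for subset enumeration
.combn_cached <- function(n, n1) {
  key <- paste0(n, "_", n1)
  got <- .ctot_cache[[key]]
  if (is.null(got)) {
    got <- utils::combn(n, n1)
    .ctot_cache[[key]] <- got
  }
  got
}

# Risk table, weights, statistic and per-observation scores from raw vectors.
# `value` holds the observed delta-Cq for events and the censoring bound for
# censored observations; censored values tied with an event value remain in
# the risk set at that value (events precede censorings at equal values).
.risk_core <- function(value, phi, group, fh_p = 0, fh_q = 0) {
  ev <- value[phi == 1L]
  if (!length(ev)) {
    return(list(d = numeric(0), u = 0, v = 0, scores = rep(0, length(value))))
  }
  d <- sort(unique(ev))
  r <- length(d)
  atrisk <- outer(value, d, `>=`)            # n x r
  in1 <- group == 1L
  p <- .colSums(atrisk, nrow(atrisk), r)
  p1 <- .colSums(atrisk & in1, nrow(atrisk), r)
  idx <- match(value, d)                     # row of own event value (events)
  ev_idx <- idx[phi == 1L]
  o <- tabulate(ev_idx, nbins = r)
  o1 <- tabulate(ev_idx[in1[phi == 1L]], nbins = r)
  e1 <- o * p1 / p
  v1 <- ifelse(p > 1, o * (p1 / p) * (1 - p1 / p) * (p - o) / (p - 1), 0)
  s_minus <- cumprod(c(1, (1 - o / p)))[seq_len(r)]
  w <- s_minus^fh_p * (1 - s_minus)^fh_q    # 0^0 == 1 in R, as required
  u <- sum(w * (o1 - e1))
  v <- sum(w^2 * v1)
  # permutation-equivalent per-observation scores:
  # c_i = phi_i * w(y_i) - sum_{d <= y_i} w_d o_d / p_d
  cum_haz <- cumsum(w * o / p)
  pos <- findInterval(value, d)             # count of d <= value
  scores <- ifelse(pos > 0, -cum_haz[pmax(pos, 1L)], 0)
  has_event <- phi == 1L
  scores[has_event] <- scores[has_event] + w[idx[has_event]]
  list(d = d, p = p, p1 = p1, o = o, o1 = o1, e1 = e1, v1 = v1,
       s_minus = s_minus, w = w, u = u, v = v, scores = scores)
}

.risk_tibble <- function(core) {
  tibble::tibble(
    d = core$d, p_d1 = core$p1, p_d2 = core$p - core$p1, p_d = core$p,
    o_d1 = core$o1, o_d2 = core$o - core$o1, o_d = core$o,
    e_d1 = core$e1, v_d1 = core$v1, s_minus = core$s_minus, w_d = core$w
  )
}

.check_alternative <- function(alternative) {
  match.arg(alternative, c("two_sided", "rate1_greater", "rate1_less"))
}

#' Tabulate risk sets and hypergeometric moments at each detection point
#'
#' For every distinct normalized value d at which at least one sample reaches
#' the fluorescence threshold, counts the samples still "at risk" of detection
#' (observed or censored value >= d) and those detected exactly at d, by
#' group. Conditional on the margins, the group-1 detection count follows a
#' hypergeometric distribution, giving the expected count
#' `e_d1 = o_d * p_d1 / p_d` and finite-population variance
#' `v_d1 = o_d (p_d1/p_d)(1 - p_d1/p_d)(p_d - o_d)/(p_d - 1)` (0 when
#' `p_d <= 1`).
#'
#' @param data A `cq_normalized` tibble ([normalize_target()] /
#'   [new_normalized()]).
#' @return A tibble with one row per detection point (ascending `d`):
#'   `d, p_d1, p_d2, p_d, o_d1, o_d2, o_d, e_d1, v_d1, s_minus, w_d`.
#'   `s_minus` is the pooled Kaplan-Meier left limit (see [km_left_limits()])
#'   and `w_d` is initialized to the unweighted value 1.
#' @export
build_risk_table <- function(data) {
  stopifnot(inherits(data, "cq_normalized"))
  core <- .risk_core(data$delta_y, data$phi, data$group)
  if (!length(core$d)) {
    return(tibble::tibble(
      d = numeric(0), p_d1 = integer(0), p_d2 = integer(0), p_d = integer(0),
      o_d1 = integer(0), o_d2 = integer(0), o_d = integer(0),
      e_d1 = numeric(0), v_d1 = numeric(0), s_minus = numeric(0),
      w_d = numeric(0)
    ))
  }
  .risk_tibble(core)
}

#' Pooled Kaplan-Meier left limits over a risk table
#'
#' Fills `s_minus`, the pooled product-limit survivor estimate just before
#' each detection point: `s_minus = 1` at the first point and
#' `prod_{d' < d} (1 - o_d'/p_d')` after.
#'
#' @param rows A risk table from [build_risk_table()] (rows ascending in `d`).
#' @return The same tibble with `s_minus` (re)computed.
#' @export
km_left_limits <- function(rows) {
  r <- nrow(rows)
  if (!r) return(rows)
  rows$s_minus <- cumprod(c(1, (1 - rows$o_d / rows$p_d)))[seq_len(r)]
  rows
}

#' Fleming-Harrington weights
#'
#' Weights each detection point by `s_minus^p * (1 - s_minus)^q` with the
#' convention `0^0 = 1`. `p = q = 0` gives unit weights (the plain log-rank
#' test); `p > 0` up-weights early detection points, `q > 0` late ones.
#'
#' @param rows Risk table with `s_minus` filled ([km_left_limits()]).
#' @param p,q Nonnegative Fleming-Harrington exponents.
#' @return The same tibble with `w_d` filled.
#' @export
fh_weights <- function(rows, p = 0, q = 0) {
  if (p < 0 || q < 0) stop("Fleming-Harrington exponents must be nonnegative",
                           call. = FALSE)
  rows$w_d <- rows$s_minus^p * (1 - rows$s_minus)^q
  rows
}

#' Weighted observed-minus-expected statistic and its variance
#'
#' `u = sum_d w_d (o_d1 - e_d1)` and `v = sum_d w_d^2 v_d1` over the risk
#' table. `u > 0` means group 1 reaches the fluorescence threshold in excess
#' of expectation (a higher threshold-crossing rate, i.e. lower delta-Cq,
#' higher target level).
#'
#' @param rows Risk table with weights filled.
#' @return A list with elements `u` and `v` (both 0 for an empty table).
#' @export
linear_statistic <- function(rows) {
  list(u = sum(rows$w_d * (rows$o_d1 - rows$e_d1)),
       v = sum(rows$w_d^2 * rows$v_d1))
}

#' Per-observation log-rank scores
#'
#' Reformulates the weighted statistic as a sum of per-observation scores,
#' `c_i = phi_i w(y_i) - sum_{d <= y_i} w_d o_d / p_d`, where y_i is the
#' observed value or censoring bound. The group-1 score sum equals `u` from
#' [linear_statistic()] exactly, which is what makes label permutation (with
#' scores held fixed) equivalent to recomputing the statistic per labeling.
#'
#' @param data A `cq_normalized` tibble.
#' @param rows Risk table with weights filled; must come from the same data.
#' @return Numeric vector of scores, one per row of `data`.
#' @export
logrank_scores <- function(data, rows) {
  stopifnot(inherits(data, "cq_normalized"))
  r <- nrow(rows)
  if (!r) return(rep(0, nrow(data)))
  cum_haz <- cumsum(rows$w_d * rows$o_d / rows$p_d)
  pos <- findInterval(data$delta_y, rows$d)
  scores <- ifelse(pos > 0, -cum_haz[pmax(pos, 1L)], 0)
  has_event <- data$phi == 1L
  scores[has_event] <- scores[has_event] + rows$w_d[match(data$delta_y[has_event], rows$d)]
  scores
}

# shared extremeness rules for exact and Monte Carlo permutation p-values
.perm_tol <- function(scores, tol) {
  if (!is.null(tol)) return(tol)
  1e-12 * max(abs(scores), 1) * length(scores)
}

.perm_count <- function(sums, t_obs, mu, alternative, tol) {
  switch(alternative,
    two_sided = sum(abs(sums - mu) >= abs(t_obs - mu) - tol),
    rate1_greater = sum(sums >= t_obs - tol),
    rate1_less = sum(sums <= t_obs + tol)
  )
}

#' Exact permutation p-value of a score-sum statistic
#'
#' Enumerates all `choose(n, n1)` relabelings, computing the group-1 score sum
#' T for each. The two-sided p-value counts labelings with `|T - mu|` at least
#' the observed absolute deviation, where `mu = n1 * mean(scores)` is the
#' permutation mean; one-sided alternatives count `T >= T_obs` (group-1 rate
#' greater) or `T <= T_obs`. The observed labeling is always counted, so
#' p lies in (0, 1], and the p-value is a multiple of `1/choose(n, n1)`.
#'
#' @param scores Per-observation scores ([logrank_scores()]), group 1 first.
#' @param n1 Size of group 1 (the first `n1` scores).
#' @param alternative `"two_sided"` (default), `"rate1_greater"`,
#'   `"rate1_less"`.
#' @param tol Absolute tie tolerance for floating-point comparisons; default
#'   `1e-12 * max(|scores|) * n` so mathematically tied statistics count as
#'   ties.
#' @param enumeration_limit Refuse enumeration beyond this many labelings.
#' @return The p-value.
#' @export
exact_permutation_pvalue <- function(scores, n1,
                                     alternative = "two_sided",
                                     tol = NULL,
                                     enumeration_limit = 2e5) {
  alternative <- .check_alternative(alternative)
  n <- length(scores)
  stopifnot(n1 >= 1, n1 <= n - 1)
  n_comb <- choose(n, n1)
  if (n_comb > enumeration_limit) {
    stop("choose(", n, ", ", n1, ") = ", n_comb,
         " labelings exceed the enumeration limit; use ",
         "montecarlo_permutation_pvalue()", call. = FALSE)
  }
  tol <- .perm_tol(scores, tol)
  cmb <- .combn_cached(n, n1)
  sums <- .colSums(scores[cmb], n1, ncol(cmb))
  t_obs <- sum(scores[seq_len(n1)])
  mu <- n1 * mean(scores)
  .perm_count(sums, t_obs, mu, alternative, tol) / n_comb
}

#' Monte Carlo permutation p-value
#'
#' Resampling fallback when full enumeration is infeasible: draws `B` random
#' relabelings and reports `(1 + #extreme) / (B + 1)` under the same
#' extremeness rules as [exact_permutation_pvalue()].
#'
#' @inheritParams exact_permutation_pvalue
#' @param B Number of resamples (>= 1000).
#' @param seed Integer seed; the RNG state of the session is left untouched.
#' @return The p-value.
#' @export
montecarlo_permutation_pvalue <- function(scores, n1, B = 1e5, seed = 1L,
                                          alternative = "two_sided",
                                          tol = NULL) {
  alternative <- .check_alternative(alternative)
  stopifnot(B >= 1000)
  n <- length(scores)
  tol <- .perm_tol(scores, tol)
  t_obs <- sum(scores[seq_len(n1)])
  mu <- n1 * mean(scores)
  sums <- withr::with_seed(seed, {
    vapply(seq_len(B), function(i) sum(scores[sample.int(n, n1)]), numeric(1))
  })
  (1 + .perm_count(sums, t_obs, mu, alternative, tol)) / (B + 1)
}

#' Normal-approximation p-value
#'
#' Large-sample reference: `z = u / sqrt(v)` compared with the standard
#' normal. Degenerate variance (`v = 0`) yields p = 1.
#'
#' @param u,v Statistic and variance from [linear_statistic()].
#' @param alternative See [exact_permutation_pvalue()].
#' @return The p-value.
#' @export
asymptotic_pvalue <- function(u, v, alternative = "two_sided") {
  alternative <- .check_alternative(alternative)
  if (v <= 0) return(1)
  z <- u / sqrt(v)
  switch(alternative,
    two_sided = 2 * stats::pnorm(-abs(z)),
    rate1_greater = stats::pnorm(-z),
    rate1_less = stats::pnorm(z)
  )
}

# fast path shared by ctot_test() and the simulation harness: raw vectors in,
# minimal list out
.ctot_core <- function(value, phi, group, fh_p = 0, fh_q = 0,
                       alternative = "two_sided", pvalue_mode = "auto",
                       enumeration_limit = 2e5, B = 1e5, seed = NULL) {
  n <- length(value)
  n1 <- sum(group == 1L)
  core <- .risk_core(value, phi, group, fh_p, fh_q)
  degenerate <- NULL
  if (!length(core$d)) degenerate <- "no detection points"
  else if (core$v <= 0) degenerate <- "zero permutation variance"

  n_comb <- choose(n, n1)
  if (pvalue_mode == "auto") {
    pvalue_mode <- if (n_comb <= enumeration_limit) "exact" else "montecarlo"
  }
  n_used <- NA_integer_

  if (!is.null(degenerate)) {
    p <- 1
  } else if (pvalue_mode == "exact") {
    # enumerate directly on the ordered scores (group 1 occupies which rows?)
    ord <- order(group)       # scores reordered so group 1 comes first
    p <- exact_permutation_pvalue(core$scores[ord], n1, alternative,
                                  enumeration_limit = enumeration_limit)
    n_used <- as.integer(n_comb)
  } else if (pvalue_mode == "montecarlo") {
    ord <- order(group)
    p <- montecarlo_permutation_pvalue(core$scores[ord], n1, B = B,
                                       seed = if (is.null(seed)) 1L else seed,
                                       alternative = alternative)
    n_used <- as.integer(B)
  } else {
    p <- asymptotic_pvalue(core$u, core$v, alternative)
  }

  z <- if (core$v > 0) core$u / sqrt(core$v) else 0
  list(u = core$u, v = core$v, z = z, p_value = p, pvalue_mode = pvalue_mode,
       degenerate = degenerate, n_used = n_used, core = core,
       scores = core$scores)
}

#' The cycle-to-threshold (CTOT) test
#'
#' Two-group comparison of normalized Cq outcomes with right-censored
#' "Undetermined" observations, treating threshold crossing as the event of
#' interest. Under the null of a common threshold-crossing rate, the group-1
#' detection count at each distinct detection point is hypergeometric given
#' the risk-set margins; the test statistic sums the weighted observed minus
#' expected counts over all detection points, and its p-value comes from the
#' complete permutation distribution of group labels (exact), a Monte Carlo
#' sample of it, or the standard normal approximation.
#'
#' With Fleming-Harrington exponents `fh_p = fh_q = 0` this is the exact
#' log-rank test; nonzero exponents weight early/late detection points. The
#' test depends on the data only through ranks and the censoring pattern, so
#' any strictly increasing transform of the normalized values (applied to
#' events and censoring bounds alike) leaves the p-value unchanged.
#'
#' @param data A `cq_normalized` tibble.
#' @param fh_p,fh_q Nonnegative Fleming-Harrington exponents (default 0, 0).
#' @param alternative `"two_sided"` (default), `"rate1_greater"` (group 1
#'   crosses the threshold at a higher rate, i.e. lower delta-Cq),
#'   `"rate1_less"`.
#' @param pvalue_mode `"auto"` (exact when `choose(n, n1)` is within
#'   `enumeration_limit`, else Monte Carlo), `"exact"`, `"montecarlo"`,
#'   `"asymptotic"`.
#' @param enumeration_limit Maximum number of labelings for exact enumeration.
#' @param B Monte Carlo resamples.
#' @param seed Seed for Monte Carlo mode.
#' @return An object of class `ctot_test`: a list with `statistic_u`,
#'   `variance_v`, `z`, `p_value`, `pvalue_mode`, `alternative`, `fh_p`,
#'   `fh_q`, `n1`, `n2`, `n_enumerated`, `degenerate` (reason string or
#'   `NULL`), `risk_table`, `scores`, `data`. Degenerate inputs (no detection
#'   points, or zero permutation variance) give p = 1 with a reason rather
#'   than an error, so simulation harnesses can count them as non-rejections.
#' @seealso [tidy.ctot_test()], [glance.ctot_test()], [autoplot.ctot_test()]
#' @export
#' @examples
#' d <- new_normalized(c(1, 3), c(2, 4), phi2 = c(1, 0))
#' ctot_test(d)
ctot_test <- function(data, fh_p = 0, fh_q = 0,
                      alternative = c("two_sided", "rate1_greater", "rate1_less"),
                      pvalue_mode = c("auto", "exact", "montecarlo", "asymptotic"),
                      enumeration_limit = 2e5, B = 1e5, seed = NULL) {
  stopifnot(inherits(data, "cq_normalized"))
  alternative <- match.arg(alternative)
  pvalue_mode <- match.arg(pvalue_mode)
  if (fh_p < 0 || fh_q < 0) stop("Fleming-Harrington exponents must be nonnegative",
                                 call. = FALSE)
  core <- .ctot_core(data$delta_y, data$phi, data$group, fh_p, fh_q,
                     alternative, pvalue_mode, enumeration_limit, B, seed)
  structure(
    list(
      statistic_u = core$u, variance_v = core$v, z = core$z,
      p_value = core$p_value, pvalue_mode = core$pvalue_mode,
      alternative = alternative, fh_p = fh_p, fh_q = fh_q,
      n1 = attr(data, "n1"), n2 = attr(data, "n2"),
      n_enumerated = core$n_used, seed = seed,
      degenerate = core$degenerate,
      risk_table = if (length(core$core$d)) .risk_tibble(core$core) else build_risk_table(data),
      scores = core$scores,
      data = data
    ),
    class = "ctot_test"
  )
}

#' @export
print.ctot_test <- function(x, ...) {
  cat("Cycle-to-threshold (CTOT) test\n")
  cat("  groups: n1 =", x$n1, ", n2 =", x$n2,
      sprintf(" (FH p = %g, q = %g)\n", x$fh_p, x$fh_q))
  cat(sprintf("  U = %.4f, V = %.4f, Z = %.4f\n",
              x$statistic_u, x$variance_v, x$z))
  cat(sprintf("  p-value = %.6g  [%s, %s]\n",
              x$p_value, x$pvalue_mode, x$alternative))
  if (!is.null(x$degenerate)) cat("  degenerate:", x$degenerate, "\n")
  invisible(x)
}
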