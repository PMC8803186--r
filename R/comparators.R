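# Comparator analysis strategies for censored Cq data: MC (substitute the
# cutoff), CO (drop censored samples), CNA (decline to analyze), and the
# simulation-only BFD benchmark on the uncensored truth. Each is paired with
# a two-independent-groups t-test.

#' MC transform: substitute the quality cutoff for uncertain values
#'
#' Uncertain observations (phi = 0) are set to their censoring bound
#' `c1 - normalizer Cq`; determined observations keep their delta-Cq. This is
#' the common "maximum cycle" substitution strategy.
#'
#' @param data A `cq_normalized` tibble.
#' @return A list with numeric vectors `group1` and `group2`.
#' @export
mc_transform <- function(data) {
  stopifnot(inherits(data, "cq_normalized"))
  # the stored delta_y of a censored observation *is* the bound c1 - normalizer
  list(group1 = data$delta_y[data$group == 1L],
       group2 = data$delta_y[data$group == 2L])
}

#' CO transform: drop uncertain observations
#'
#' Complete-observation strategy: censored samples are removed, so group
#' sizes may shrink (possibly to zero).
#'
#' @param data A `cq_normalized` tibble.
#' @return A list with numeric vectors `group1` and `group2` of the retained
#'   (phi = 1) values.
#' @export
co_transform <- function(data) {
  stopifnot(inherits(data, "cq_normalized"))
  keep <- data$phi == 1L
  list(group1 = data$delta_y[keep & data$group == 1L],
       group2 = data$delta_y[keep & data$group == 2L])
}

#' Is the choose-not-to-analyze strategy applicable?
#'
#' CNA analyzes a target only when every observation in both groups is
#' certainly determined; any censoring disqualifies the target.
#'
#' @param data A `cq_normalized` tibble.
#' @return `TRUE` iff all phi = 1.
#' @export
cna_applicable <- function(data) {
  stopifnot(inherits(data, "cq_normalized"))
  all(data$phi == 1L)
}

#' Two-independent-groups t-test
#'
#' Welch's unequal-variance form by default (`var_equal = FALSE`), or the
#' pooled-variance Student form. Written for the simulation harness:
#' undersized or zero-variance input yields a degenerate record (p = 1 with a
#' reason), never an error.
#'
#' @param x,y Numeric vectors for groups 1 and 2.
#' @param alternative `"two_sided"` (default), `"rate1_greater"`,
#'   `"rate1_less"` — named for consistency with [ctot_test()]; a *greater*
#'   group-1 threshold-crossing rate corresponds to *lower* group-1 values,
#'   so `"rate1_greater"` tests mean(x) < mean(y).
#' @param var_equal Use the pooled-variance form.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean1`, `mean2`,
#'   `usable` (logical), `degenerate_reason`.
#' @export
t_test_two_groups <- function(x, y, alternative = "two_sided",
                              var_equal = FALSE) {
  alternative <- .check_alternative(alternative)
  degen <- function(reason) tibble::tibble(
    statistic = NA_real_, df = NA_real_, p_value = 1,
    mean1 = if (length(x)) mean(x) else NA_real_,
    mean2 = if (length(y)) mean(y) else NA_real_,
    usable = FALSE, degenerate_reason = reason
  )
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) return(degen("fewer than 2 observations in a group"))
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      return(tibble::tibble(statistic = 0, df = nx + ny - 2, p_value = 1,
                            mean1 = mean(x), mean2 = mean(y), usable = TRUE,
                            degenerate_reason = NA_character_))
    }
    return(degen("zero variance in both groups"))
  }
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  if (se == 0) return(degen("zero standard error"))
  tstat <- (mean(x) - mean(y)) / se
  p <- switch(alternative,
    two_sided = 2 * stats::pt(-abs(tstat), df),
    rate1_greater = stats::pt(tstat, df),   # rate1 greater <=> mean1 lower
    rate1_less = stats::pt(-tstat, df)
  )
  tibble::tibble(statistic = tstat, df = df, p_value = p,
                 mean1 = mean(x), mean2 = mean(y), usable = TRUE,
                 degenerate_reason = NA_character_)
}

# minimal two-sided Welch/pooled p-value for the simulation loops;
# NA signals a degenerate comparison
.ttest_fast <- function(x, y, var_equal = FALSE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) return(NA_real_)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) return(if (mean(x) == mean(y)) 1 else NA_real_)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  if (se == 0) return(NA_real_)
  2 * stats::pt(-abs((mean(x) - mean(y)) / se), df)
}

#' Run one analysis strategy on a normalized dataset
#'
#' Dispatches to the requested strategy and returns a uniform one-row record:
#' * `"ctot"` — exact CTOT test ([ctot_test()]);
#' * `"mc"` — t-test after cutoff substitution ([mc_transform()]);
#' * `"co"` — t-test on complete observations ([co_transform()]; degenerate
#'   when a group retains fewer than 2);
#' * `"cna"` — t-test only when no censoring is present, otherwise a
#'   "not analyzed" record;
#' * `"bfd"` — t-test on the uncensored simulation truth (requires
#'   `true_delta_y`).
#'
#' @param method One of `"ctot"`, `"mc"`, `"co"`, `"cna"`, `"bfd"`.
#' @param data A `cq_normalized` tibble.
#' @param true_delta_y For `"bfd"` only: list with numeric `group1`,
#'   `group2` of true uncensored normalized values.
#' @param alternative Passed through to the underlying test.
#' @param var_equal t-test variant for the t-based strategies.
#' @param ... Further arguments to [ctot_test()].
#' @return A one-row tibble: `method`, `usable`, `analyzed`, `n1`, `n2`,
#'   `statistic`, `p_value`, `degenerate_reason`.
#' @export
run_method <- function(method = c("ctot", "mc", "co", "cna", "bfd"),
                       data, true_delta_y = NULL,
                       alternative = "two_sided", var_equal = FALSE, ...) {
  method <- match.arg(method)
  stopifnot(inherits(data, "cq_normalized"))
  row <- function(usable, analyzed, n1, n2, statistic, p, reason) {
    tibble::tibble(method = method, usable = usable, analyzed = analyzed,
                   n1 = n1, n2 = n2, statistic = statistic, p_value = p,
                   degenerate_reason = reason)
  }
  if (method == "ctot") {
    fit <- ctot_test(data, alternative = alternative, ...)
    return(row(is.null(fit$degenerate), TRUE, fit$n1, fit$n2, fit$z,
               fit$p_value,
               if (is.null(fit$degenerate)) NA_character_ else fit$degenerate))
  }
  if (method == "bfd") {
    if (is.null(true_delta_y)) {
      stop("BFD requires `true_delta_y` (the uncensored simulation truth)",
           call. = FALSE)
    }
    vals <- true_delta_y
  } else if (method == "mc") {
    vals <- mc_transform(data)
  } else if (method == "co") {
    vals <- co_transform(data)
  } else { # cna
    if (!cna_applicable(data)) {
      return(row(FALSE, FALSE, attr(data, "n1"), attr(data, "n2"),
                 NA_real_, NA_real_, "uncertain observations present: not analyzed"))
    }
    vals <- mc_transform(data)  # no censoring, so these are the observed values
  }
  tt <- t_test_two_groups(vals$group1, vals$group2, alternative, var_equal)
  row(tt$usable, TRUE, length(vals$group1), length(vals$group2),
      tt$statistic, tt$p_value, tt$degenerate_reason)
}

#' Run several strategies side by side
#'
#' @param data A `cq_normalized` tibble.
#' @param methods Character vector of strategies (see [run_method()]).
#' @inheritParams run_method
#' @return Row-bound tibble of [run_method()] records.
#' @export
compare_methods <- function(data, methods = c("ctot", "mc", "co", "cna"),
                            true_delta_y = NULL, alternative = "two_sided",
                            var_equal = FALSE, ...) {
  purrr::map_dfr(methods, run_method, data = data,
                 true_delta_y = true_delta_y, alternative = alternative,
                 var_equal = var_equal, ...)
}
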