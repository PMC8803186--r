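#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a CTOT test
#'
#' @param x A `ctot_test` object.
#' @param ... Unused.
#' @return A one-row tibble with the statistic, variance, z, p-value and the
#'   test configuration.
#' @method tidy ctot_test
#' @export
tidy.ctot_test <- function(x, ...) {
  tibble::tibble(
    statistic_u = x$statistic_u,
    variance_v = x$variance_v,
    z = x$z,
    p_value = x$p_value,
    pvalue_mode = x$pvalue_mode,
    alternative = x$alternative,
    fh_p = x$fh_p,
    fh_q = x$fh_q,
    degenerate = !is.null(x$degenerate),
    degenerate_reason = x$degenerate %||% NA_character_
  )
}

#' Glance at a CTOT test
#'
#' @param x A `ctot_test` object.
#' @param ... Unused.
#' @return A one-row tibble of fit-level summaries: group sizes, numbers of
#'   censored observations, detection points, enumerated labelings.
#' @method glance ctot_test
#' @export
glance.ctot_test <- function(x, ...) {
  tibble::tibble(
    n1 = x$n1, n2 = x$n2,
    n_censored = sum(x$data$phi == 0L),
    n_detection_points = nrow(x$risk_table),
    n_enumerated = x$n_enumerated,
    p_value = x$p_value
  )
}

#' @rdname run_power_study
#' @param x A `ctot_power_study` object.
#' @param ... Unused.
#' @method tidy ctot_power_study
#' @export
tidy.ctot_power_study <- function(x, ...) x$results

#' @rdname run_type1_study
#' @param x A `ctot_type1_study` object.
#' @param ... Unused.
#' @method tidy ctot_type1_study
#' @export
tidy.ctot_type1_study <- function(x, ...) x$results
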