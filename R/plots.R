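# ggplot2 displays for test objects and study reports.

# per-group Kaplan-Meier step data on the normalized scale
.km_steps <- function(data) {
  purrr::map_dfr(1:2, function(k) {
    sel <- data$group == k
    value <- data$delta_y[sel]
    phi <- data$phi[sel]
    ev <- sort(unique(value[phi == 1L]))
    s <- 1
    steps <- tibble::tibble(delta_y = min(c(value, 0)), s = 1)
    for (d in ev) {
      p <- sum(value >= d)
      o <- sum(value == d & phi == 1L)
      s <- s * (1 - o / p)
      steps <- dplyr::bind_rows(steps, tibble::tibble(delta_y = d, s = s))
    }
    steps$group <- factor(attr(data, "group_labels")[k],
                          levels = attr(data, "group_labels"))
    steps
  })
}

#' Plot a CTOT test as group-wise threshold-crossing curves
#'
#' Kaplan-Meier-style curves of the fraction of samples not yet having
#' crossed the fluorescence threshold, by normalized cycle, with censored
#' observations marked at their bounds.
#'
#' @param object A `ctot_test` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ctot_test
#' @export
autoplot.ctot_test <- function(object, ...) {
  data <- object$data
  steps <- .km_steps(data)
  cens <- data[data$phi == 0L, ]
  p <- ggplot2::ggplot(steps, ggplot2::aes(x = .data$delta_y, y = .data$s,
                                           colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::labs(
      x = expression(paste("normalized cycle ", Delta, "Cq")),
      y = "fraction not yet at threshold",
      colour = "group",
      subtitle = sprintf("CTOT p = %.4g (%s, %s)", object$p_value,
                         object$pvalue_mode, object$alternative)
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (nrow(cens)) {
    cens$group <- factor(attr(data, "group_labels")[cens$group],
                         levels = attr(data, "group_labels"))
    p <- p + ggplot2::geom_point(
      data = cens,
      ggplot2::aes(x = .data$delta_y, y = 0, colour = .data$group),
      shape = 3, size = 2, inherit.aes = FALSE
    )
  }
  p
}

#' @export
plot.ctot_test <- function(x, ...) print(autoplot.ctot_test(x, ...))

#' Plot a power study report
#'
#' Empirical power per method and family with Monte Carlo 95% intervals.
#'
#' @param object A `ctot_power_study` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ctot_power_study
#' @export
autoplot.ctot_power_study <- function(object, ...) {
  res <- object$results
  ggplot2::ggplot(res, ggplot2::aes(x = .data$method, y = .data$power)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper), width = 0.2) +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(y = "empirical power (replicates with uncertain data)",
                  x = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a type-I-error study report
#'
#' Per-scenario empirical rejection rates with Monte Carlo 95% intervals and
#' the nominal level as a reference line.
#'
#' @param object A `ctot_type1_study` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ctot_type1_study
#' @export
autoplot.ctot_type1_study <- function(object, ...) {
  res <- object$results
  res$scenario <- sprintf("beta0=%g, sigma=%g", res$beta0, res$sigma)
  ggplot2::ggplot(res, ggplot2::aes(x = .data$method, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper), width = 0.2) +
    ggplot2::geom_hline(yintercept = object$config$alpha, linetype = 2) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(y = "empirical type-I error rate", x = NULL) +
    ggplot2::theme_minimal()
}
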