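#' Interpretable summaries of a censored Cq comparison
#'
#' Reports, per group, the proportion of uncertain quantifications (phi = 0),
#' the Kaplan-Meier median of the normalized outcome (the smallest detection
#' point at which the group survivor estimate drops to 0.5 or below; `NA`,
#' "not reached", when censoring keeps it above 0.5), and the observed and
#' expected detection totals from the pooled unweighted risk table. The
#' threshold-crossing rate ratio — the analogue of a hazard ratio — is
#' estimated by the O/E ratio `(o1/e1)/(o2/e2)`, defined only when both
#' expected totals and the group-2 observed total are positive.
#'
#' @param data A `cq_normalized` tibble.
#' @return An object of class `ctot_summary`: a list with `by_group` (a
#'   tibble: `group`, `label`, `n`, `n_uncertain`, `proportion_uncertain`,
#'   `km_median_delta_y`, `o`, `e`), `ctot_ratio` (`NA` with
#'   `ratio_defined = FALSE` when undefined), `c1`, `target_id`.
#' @export
#' @examples
#' d <- new_normalized(c(1, 3), c(2, 4), phi2 = c(1, 0))
#' ctot_summary(d)
ctot_summary <- function(data) {
  stopifnot(inherits(data, "cq_normalized"))
  rows <- build_risk_table(data)
  o1 <- sum(rows$o_d1); e1 <- sum(rows$e_d1)
  o2 <- sum(rows$o_d2); e2 <- sum(rows$o_d - rows$e_d1)

  km_median <- function(value, phi) {
    ev <- sort(unique(value[phi == 1L]))
    if (!length(ev)) return(NA_real_)
    p <- vapply(ev, function(d) sum(value >= d), numeric(1))
    o <- vapply(ev, function(d) sum(value == d & phi == 1L), numeric(1))
    s <- cumprod(1 - o / p)
    hit <- which(s <= 0.5 + 1e-12)
    if (!length(hit)) NA_real_ else ev[hit[1]]
  }

  by_group <- purrr::map_dfr(1:2, function(k) {
    sel <- data$group == k
    tibble::tibble(
      group = k,
      label = attr(data, "group_labels")[k],
      n = sum(sel),
      n_uncertain = sum(sel & data$phi == 0L),
      proportion_uncertain = sum(sel & data$phi == 0L) / sum(sel),
      km_median_delta_y = km_median(data$delta_y[sel], data$phi[sel]),
      o = if (k == 1) o1 else o2,
      e = if (k == 1) e1 else e2
    )
  })

  defined <- e1 > 0 && e2 > 0 && o2 > 0
  structure(
    list(
      by_group = by_group,
      ctot_ratio = if (defined) (o1 / e1) / (o2 / e2) else NA_real_,
      ratio_defined = defined,
      c1 = attr(data, "c1"),
      target_id = attr(data, "target_id")
    ),
    class = "ctot_summary"
  )
}

#' @export
print.ctot_summary <- function(x, ...) {
  cat("Cycle-to-threshold summary for target '", x$target_id,
      "' (c1 = ", x$c1, ")\n", sep = "")
  print(x$by_group)
  if (x$ratio_defined) {
    cat(sprintf("Threshold-crossing rate ratio (O/E ratio, group1/group2): %.4f\n",
                x$ctot_ratio))
  } else {
    cat("Threshold-crossing rate ratio: undefined (a group lacks detections)\n")
  }
  invisible(x)
}

#' @rdname ctot_summary
#' @param x A `ctot_summary` object.
#' @param ... Unused.
#' @method tidy ctot_summary
#' @export
tidy.ctot_summary <- function(x, ...) {
  out <- x$by_group
  out$ctot_ratio <- x$ctot_ratio
  out
}
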