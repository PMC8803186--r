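#' Normalize one target against the per-sample normalizer, propagating censoring
#'
#' Computes the normalized outcome pair (delta-Cq, phi) for every sample
#' carrying a record of `target`. With Y the target Cq, Y_r the normalizer Cq
#' of the same sample and C1 the maximum quality cycle:
#'
#' * phi = 1 (threshold certainly reached) when Y is reported and Y < C1;
#'   then `delta_y = Y - Y_r`.
#' * phi = 0 (uncertain / right-censored) when Y is undetermined or Y >= C1;
#'   then `delta_y = C1 - Y_r`, a per-sample *lower bound* on the true
#'   normalized value. The boundary Y = C1 is censored (phi is the indicator
#'   of a strict inequality).
#'
#' Because normalizer Cq values differ between samples, censored observations
#' carry observation-specific censoring bounds; all downstream machinery
#' works with those per-observation bounds, not a single global cutoff.
#'
#' @param data A [as_cq_data()] tibble.
#' @param target Target id to analyze.
#' @param c1 Maximum quality cycle; defaults to the dataset attribute.
#' @param group_order Optional length-2 character vector giving which label is
#'   group 1 and which group 2 (direction matters for one-sided tests).
#'   Defaults to sorted order of the two labels.
#'
#' @return A tibble of class `cq_normalized` with one row per analyzed sample:
#'   `sample_id`, `group_label`, `group` (1 or 2), `delta_y` (the observed
#'   value when `phi == 1`, the censoring bound when `phi == 0`), `phi`,
#'   `raw_cq`, `normalizer_cq`. Attributes: `target_id`, `c1`, `group_labels`,
#'   `n1`, `n2`.
#'
#' @details Samples with a normalizer record that is undetermined or at/above
#'   `c1` trigger an error: the method assumes a well-observed normalizer Cq.
#'   Samples lacking a record for `target` altogether (missingness, not
#'   censoring) are excluded with a warning.
#' @export
#' @examples
#' df <- tibble::tibble(
#'   sample_id = rep(c("S1", "S2", "S3", "S4"), each = 2),
#'   group_label = rep(c("a", "a", "b", "b"), each = 2),
#'   target_id = rep(c("m1", "norm"), 4),
#'   cq = c(30, 25, NA, 25, 33, 26, 35, 24),
#'   is_determined = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
#' )
#' d <- as_cq_data(df, c1 = 40, normalizer_target = "norm")
#' normalize_target(d, "m1")
normalize_target <- function(data, target, c1 = NULL, group_order = NULL) {
  stopifnot(inherits(data, "cq_data"))
  if (is.null(c1)) c1 <- attr(data, "c1")
  normalizer <- attr(data, "normalizer_target")

  norm_rows <- data[data$target_id == normalizer, ]
  tgt_rows <- data[data$target_id == target, ]
  if (!nrow(tgt_rows)) {
    stop("no records for target '", target, "'", call. = FALSE)
  }

  all_samples <- unique(data$sample_id[data$target_id != normalizer])
  missing_samples <- setdiff(all_samples, tgt_rows$sample_id)
  if (length(missing_samples)) {
    warning("sample(s) with no record for target '", target,
            "' excluded from analysis (missing, not censored): ",
            paste(missing_samples, collapse = ", "), call. = FALSE)
  }

  idx <- match(tgt_rows$sample_id, norm_rows$sample_id)
  norm_cq <- norm_rows$cq[idx]
  norm_ok <- norm_rows$is_determined[idx] & !is.na(norm_cq) & norm_cq < c1
  if (!all(norm_ok)) {
    stop("normalizer Cq undetermined or >= c1 for sample(s) ",
         paste(tgt_rows$sample_id[!norm_ok], collapse = ", "),
         "; the analysis assumes a well-observed Cq value of the normalizer",
         call. = FALSE)
  }

  labels <- sort(unique(tgt_rows$group_label))
  if (length(labels) != 2) {
    stop("exactly two group labels are required, found ", length(labels),
         ": ", paste(labels, collapse = ", "), call. = FALSE)
  }
  if (!is.null(group_order)) {
    if (!setequal(group_order, labels) || length(group_order) != 2) {
      stop("`group_order` must be a permutation of the group labels (",
           paste(labels, collapse = ", "), ")", call. = FALSE)
    }
    labels <- group_order
  }

  event <- tgt_rows$is_determined & tgt_rows$cq < c1
  out <- tibble::tibble(
    sample_id = tgt_rows$sample_id,
    group_label = tgt_rows$group_label,
    group = match(tgt_rows$group_label, labels),
    delta_y = ifelse(event, tgt_rows$cq - norm_cq, c1 - norm_cq),
    phi = as.integer(event),
    raw_cq = tgt_rows$cq,
    normalizer_cq = norm_cq
  )
  out <- out[order(out$group, out$sample_id), ]

  n1 <- sum(out$group == 1L)
  n2 <- sum(out$group == 2L)
  if (n1 == 0L || n2 == 0L) {
    stop("both groups must be nonempty after exclusions", call. = FALSE)
  }

  structure(
    out,
    target_id = target, c1 = as.numeric(c1),
    group_labels = labels, n1 = n1, n2 = n2,
    class = c("cq_normalized", class(tibble::tibble()))
  )
}

#' Build a normalized dataset directly from outcome vectors
#'
#' Convenience constructor for simulated or pre-normalized data: takes the
#' (delta-Cq, phi) pairs per group without going through raw Cq records.
#' Censored entries of `delta_y` are interpreted as per-observation censoring
#' bounds.
#'
#' @param delta_y1,delta_y2 Numeric vectors of normalized values (events) or
#'   censoring bounds (censored) for groups 1 and 2.
#' @param phi1,phi2 Event indicators (1 = threshold reached, 0 = censored);
#'   default all 1.
#' @param c1 Maximum quality cycle recorded as metadata.
#' @param target_id Label used in printing.
#' @return A `cq_normalized` tibble (see [normalize_target()]).
#' @export
new_normalized <- function(delta_y1, delta_y2,
                           phi1 = rep(1L, length(delta_y1)),
                           phi2 = rep(1L, length(delta_y2)),
                           c1 = 40, target_id = "target") {
  stopifnot(length(delta_y1) == length(phi1), length(delta_y2) == length(phi2),
            length(delta_y1) > 0, length(delta_y2) > 0,
            all(phi1 %in% 0:1), all(phi2 %in% 0:1))
  n1 <- length(delta_y1)
  n2 <- length(delta_y2)
  out <- tibble::tibble(
    sample_id = c(sprintf("g1_%02d", seq_len(n1)), sprintf("g2_%02d", seq_len(n2))),
    group_label = rep(c("1", "2"), c(n1, n2)),
    group = rep(1:2, c(n1, n2)),
    delta_y = c(as.numeric(delta_y1), as.numeric(delta_y2)),
    phi = as.integer(c(phi1, phi2)),
    raw_cq = NA_real_,
    normalizer_cq = NA_real_
  )
  structure(
    out,
    target_id = target_id, c1 = as.numeric(c1),
    group_labels = c("1", "2"), n1 = n1, n2 = n2,
    class = c("cq_normalized", class(tibble::tibble()))
  )
}

#' @export
print.cq_normalized <- function(x, ...) {
  cat("<cq_normalized> target '", attr(x, "target_id"), "', c1 = ",
      attr(x, "c1"), ", n = ", attr(x, "n1"), " + ", attr(x, "n2"),
      " (", sum(x$phi == 0L), " censored)\n", sep = "")
  NextMethod()
}
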