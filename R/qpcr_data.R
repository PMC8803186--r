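#' Assemble a Cq dataset from a data frame
#'
#' Wraps a long-format table of qPCR results (one row per sample x target)
#' together with the assay metadata the downstream analysis needs: the maximum
#' quality cycle `c1` at which Cq values become uncertain, the normalizer
#' target, and the instrument run length.
#'
#' @param data A data frame with columns `sample_id`, `group_label`,
#'   `target_id`, `cq` (numeric, `NA` when undetermined) and `is_determined`
#'   (logical). Extra columns are retained.
#' @param c1 Maximum quality cycle (cycles). Cq values at or above `c1` are
#'   treated as right-censored downstream. Must satisfy `0 < c1 <= max_cycles`.
#' @param normalizer_target Target id of the normalizer assay; every sample
#'   must carry exactly one record for it.
#' @param max_cycles Instrument run length in cycles (default 40).
#'
#' @details Validation enforces: `cq` present if and only if `is_determined`;
#'   positive finite `cq`; at most one record per (sample, target) pair; one
#'   normalizer record per sample. Censoring relative to `c1` is *not* applied
#'   here — values at or above `c1` are kept verbatim so the same dataset
#'   supports sensitivity analysis at, say, `c1 = 32` versus `c1 = 40` (see
#'   [normalize_target()]).
#'
#' @return A tibble of class `cq_data` with attributes `c1`,
#'   `normalizer_target` and `max_cycles`.
#' @seealso [read_cq_table()], [normalize_target()]
#' @export
#' @examples
#' df <- tibble::tibble(
#'   sample_id = c("S1", "S1", "S2", "S2"),
#'   group_label = c("control", "control", "treated", "treated"),
#'   target_id = c("miR-21", "norm", "miR-21", "norm"),
#'   cq = c(27.3, 25.1, NA, 24.8),
#'   is_determined = c(TRUE, TRUE, FALSE, TRUE)
#' )
#' as_cq_data(df, c1 = 40, normalizer_target = "norm")
as_cq_data <- function(data, c1, normalizer_target, max_cycles = 40) {
  data <- tibble::as_tibble(data)
  required <- c("sample_id", "group_label", "target_id", "cq", "is_determined")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("cq data is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data$sample_id <- as.character(data$sample_id)
  data$group_label <- as.character(data$group_label)
  data$target_id <- as.character(data$target_id)
  data$cq <- as.numeric(data$cq)
  data$is_determined <- as.logical(data$is_determined)

  if (!is.numeric(c1) || length(c1) != 1 || !is.finite(c1) || c1 <= 0) {
    stop("`c1` must be a single positive number of cycles", call. = FALSE)
  }
  if (c1 > max_cycles) {
    stop("`c1` (", c1, ") must not exceed `max_cycles` (", max_cycles, ")",
         call. = FALSE)
  }

  bad <- data$is_determined & (is.na(data$cq) | !is.finite(data$cq) | data$cq <= 0)
  if (any(bad)) {
    stop("determined records must carry a finite positive Cq (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  bad <- !data$is_determined & !is.na(data$cq)
  if (any(bad)) {
    stop("undetermined records must not carry a Cq value (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }

  key <- paste(data$sample_id, data$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (sample, target) pair(s): ",
         paste(gsub("\r", " / ", dup), collapse = "; "), call. = FALSE)
  }

  samples <- unique(data$sample_id)
  has_norm <- samples %in% data$sample_id[data$target_id == normalizer_target]
  if (!all(has_norm)) {
    stop("sample(s) without a normalizer ('", normalizer_target, "') record: ",
         paste(samples[!has_norm], collapse = ", "), call. = FALSE)
  }

  structure(
    data,
    c1 = as.numeric(c1),
    normalizer_target = as.character(normalizer_target),
    max_cycles = as.numeric(max_cycles),
    class = c("cq_data", class(tibble::tibble()))
  )
}

#' Default tokens an instrument uses for a reaction with no Cq
#'
#' @return Character vector of cell values interpreted as "undetermined".
#' @export
undetermined_tokens <- function() {
  c("Undetermined", "undetermined", "NA", "", "NaN")
}

#' Read a long-format qPCR Cq table
#'
#' Parses a delimited text file (CSV or TSV; delimiter auto-detected from the
#' header unless given) with one row per sample x target. Cells matching an
#' undetermined token become censoring candidates (`is_determined = FALSE`);
#' all other cells must parse as plain decimal-point numbers.
#'
#' @param path Path to the delimited file (header row required).
#' @param c1 Maximum quality cycle for downstream censoring.
#' @param normalizer_target Target id of the normalizer assay.
#' @param columns Named character vector mapping the canonical names
#'   `sample`, `group`, `target`, `cq` to the file's column names.
#' @param tokens Character vector of cell values meaning "undetermined"
#'   (default [undetermined_tokens()]).
#' @param delim Field delimiter; `NULL` (default) auto-detects `,` vs tab.
#' @param max_cycles Instrument run length (cycles).
#'
#' @return A [as_cq_data()] tibble.
#' @export
read_cq_table <- function(path, c1 = 40, normalizer_target,
                          columns = c(sample = "sample", group = "group",
                                      target = "target", cq = "cq"),
                          tokens = undetermined_tokens(),
                          delim = NULL, max_cycles = 40) {
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)

  defaults <- c(sample = "sample", group = "group", target = "target", cq = "cq")
  defaults[names(columns)] <- columns
  columns <- defaults
  missing_cols <- columns[!columns %in% names(raw)]
  if (length(missing_cols)) {
    stop("input file lacks required column(s): ",
         paste(missing_cols, collapse = ", "),
         " (available: ", paste(names(raw), collapse = ", "), ")",
         call. = FALSE)
  }

  cq_chr <- raw[[columns[["cq"]]]]
  cq_chr[is.na(cq_chr)] <- "NA"
  undet <- cq_chr %in% tokens
  cq <- rep(NA_real_, length(cq_chr))
  if (any(!undet)) {
    # strict decimal-point parsing: reject locale comma decimals outright
    parsed <- suppressWarnings(as.numeric(cq_chr[!undet]))
    bad <- is.na(parsed)
    if (any(bad)) {
      rows <- which(!undet)[bad]
      stop("non-numeric Cq cell(s) not in the undetermined-token list at data row(s) ",
           paste(rows, collapse = ", "), ": ",
           paste(unique(cq_chr[rows]), collapse = ", "),
           " (comma decimals are not accepted; use a decimal point)",
           call. = FALSE)
    }
    cq[!undet] <- parsed
  }

  as_cq_data(
    tibble::tibble(
      sample_id = raw[[columns[["sample"]]]],
      group_label = raw[[columns[["group"]]]],
      target_id = raw[[columns[["target"]]]],
      cq = cq,
      is_determined = !undet
    ),
    c1 = c1, normalizer_target = normalizer_target, max_cycles = max_cycles
  )
}

#' Write a Cq dataset back to delimited text
#'
#' Inverse of [read_cq_table()]: undetermined records are written as the token
#' `"Undetermined"`, numeric Cq values with full round-trip precision, so that
#' reading the file back reproduces the dataset exactly.
#'
#' @param data A `cq_data` tibble.
#' @param path Output path.
#' @param delim Field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(data, path, delim = ",") {
  stopifnot(inherits(data, "cq_data"))
  out <- tibble::tibble(
    sample = data$sample_id,
    group = data$group_label,
    target = data$target_id,
    cq = ifelse(data$is_determined,
                vapply(data$cq, function(x) format(x, digits = 17), character(1)),
                "Undetermined")
  )
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' @export
print.cq_data <- function(x, ...) {
  cat("<cq_data> ", length(unique(x$sample_id)), " samples, ",
      length(unique(x$target_id)), " targets, c1 = ", attr(x, "c1"),
      ", normalizer = '", attr(x, "normalizer_target"), "'\n", sep = "")
  NextMethod()
}
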