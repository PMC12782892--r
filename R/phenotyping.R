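# Retainability phenotyping: storability is scored as the maximum number
# of months of cold storage during which the fruit kept acceptable flesh
# firmness (>= 7.0 kg/cm2) or crispness (>= 0.7 kg/cm2). Retention is read
# as uninterrupted: a single sub-threshold month ends it.

#' Default acceptability thresholds (kg/cm2)
#'
#' 7.0 kg/cm2 for flesh firmness, 0.7 kg/cm2 for flesh crispness.
#' @export
retainability_thresholds <- c(firmness = 7.0, crispness = 0.7)

#' Retainability of a storage series
#'
#' The largest `t` such that the values at months `1..t` are all at or
#' above `threshold`; 0 if month 1 already fails. If every month passes the
#' result equals the series length and is right-censored (the fruit was
#' still acceptable at the last sampling), flagged via attribute
#' `"censored"`.
#'
#' @param series Numeric vector of monthly measurements (months `1..T`), or
#'   a data frame with columns `month` and `value` (ordered by `month`).
#' @param threshold Acceptability threshold, `> 0`.
#' @return Integer months, with logical attribute `"censored"`.
#' @examples
#' retainability(c(8.2, 7.6, 7.1, 6.9, 6.5), 7.0) # 3
#' @export
retainability <- function(series, threshold) {
  if (is.data.frame(series)) {
    series <- series$value[order(series$month)]
  }
  if (length(series) == 0L) {
    abort("Empty storage series.", class = "markergap_degenerate_error")
  }
  if (threshold <= 0) {
    abort("Threshold must be > 0.", class = "markergap_config_error")
  }
  fail <- which(series < threshold)
  if (length(fail) == 0L) {
    months <- length(series)
    censored <- TRUE
  } else {
    months <- fail[1] - 1L
    censored <- FALSE
  }
  structure(as.integer(months), censored = censored)
}

#' Average biological replicates of a storage series
#'
#' Per-month arithmetic mean across replicates. All replicates must cover
#' the same months (mixed lengths are an alignment error).
#'
#' @param series_df Long data frame `replicate_id`, `month`, `value`
#'   (a `trait` column, if present, must be constant).
#' @param method Aggregation method; only `"mean"` is defined.
#' @return Tibble `month`, `value` with one row per month.
#' @export
aggregate_replicates <- function(series_df, method = c("mean")) {
  method <- match.arg(method)
  series_df <- as_tibble(series_df)
  stopifnot(all(c("replicate_id", "month", "value") %in% names(series_df)))
  if ("trait" %in% names(series_df) &&
      length(unique(series_df$trait)) > 1L) {
    abort("Replicates mix traits; aggregate one trait at a time.",
          class = "markergap_alignment_error")
  }
  months_by_rep <- split(series_df$month, series_df$replicate_id)
  ref <- sort(months_by_rep[[1]])
  same <- vapply(months_by_rep, function(m) identical(sort(m), ref), logical(1))
  if (!all(same)) {
    abort(paste0("Replicate(s) ", paste(names(same)[!same], collapse = ", "),
                 " do not cover the same months as ",
                 names(months_by_rep)[1], "."),
          class = "markergap_alignment_error")
  }
  series_df |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$month)
}

#' Retainability from a replicated storage series table
#'
#' Pipeline form: averages replicates per month (default), then applies the
#' threshold. Set `per_replicate = TRUE` to threshold each replicate first
#' and average the resulting months instead.
#'
#' @param series_df Long data frame `replicate_id`, `month`, `value`.
#' @param threshold Acceptability threshold, `> 0`.
#' @param per_replicate Threshold each replicate separately and average the
#'   months? Default `FALSE` (average-then-threshold).
#' @return Tibble `months`, `censored` (one row).
#' @export
summarise_retainability <- function(series_df, threshold,
                                    per_replicate = FALSE) {
  if (per_replicate) {
    res <- series_df |>
      dplyr::group_by(.data$replicate_id) |>
      dplyr::group_map(~ retainability(.x, threshold))
    tibble(months = mean(vapply(res, as.numeric, numeric(1))),
           censored = any(vapply(res, attr, logical(1), "censored")))
  } else {
    r <- retainability(aggregate_replicates(series_df), threshold)
    tibble(months = as.numeric(r), censored = attr(r, "censored"))
  }
}
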