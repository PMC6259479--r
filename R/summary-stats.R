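# Grouped descriptive summaries: the bridge between raw replicate-level
# records and every index downstream. Two entry routes exist because field
# papers usually publish only the aggregated table: summaries can be computed
# from records or loaded pre-aggregated.

ps_summary_cols <- c(
  "site_scope", "plot_class", "medium", "tissue", "parameter",
  "n", "mean", "sd", "min", "max", "provenance"
)

#' Grouped descriptive summaries of concentration records
#'
#' Computes n, arithmetic mean, sample standard deviation (n - 1
#' denominator), minimum and maximum per group — the "Mean +/- SD" cells of a
#' biomonitoring summary table. Groups with a single observation report `sd`
#' as `NA` (the sample SD is undefined at n = 1).
#'
#' @param records A concentration-record tibble.
#' @param by Character vector of grouping columns, any subset of
#'   `site_id`, `plot_class`, `medium`, `tissue`, `parameter`. Defaults to
#'   the full table layout (plot class x medium x tissue x parameter).
#' @return A group-summary tibble: the grouping columns plus `n`, `mean`,
#'   `sd`, `min`, `max`, and `provenance = "computed"`. Grouping columns not
#'   in `by` are reported as `"all"` (site scope) or left out.
#' @export
summarize_concentrations <- function(records,
                                     by = c("plot_class", "medium", "tissue", "parameter")) {
  if (is.null(records) || nrow(records) == 0) abort("no records")
  allowed <- c("site_id", "plot_class", "medium", "tissue", "parameter")
  bad <- setdiff(by, allowed)
  if (length(bad) > 0) {
    abort(sprintf("unknown grouping column(s): %s", paste(bad, collapse = ", ")))
  }
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = if (dplyr::n() >= 2) stats::sd(.data$value) else NA_real_,
      min = min(.data$value),
      max = max(.data$value),
      .groups = "drop"
    )
  if ("site_id" %in% by) {
    out <- dplyr::rename(out, site_scope = "site_id")
  } else {
    out$site_scope <- "all"
  }
  for (col in c("plot_class", "medium", "tissue", "parameter")) {
    if (!col %in% names(out)) out[[col]] <- NA_character_
  }
  out$provenance <- "computed"
  out[ps_summary_cols]
}

#' Load a pre-aggregated summary table
#'
#' Field studies typically publish only min/max/mean/SD per group, not the
#' replicate-level values. This loader ingests such a table (CSV columns
#' `site_scope, plot_class, medium, tissue, parameter, n, mean, sd, min,
#' max`) into the same group-summary shape [summarize_concentrations()]
#' produces, marked `provenance = "pre-aggregated"` so reports can trace
#' which cells were computed and which were transcribed. Inverted min/max
#' ranges are reported through the attached validation report (see
#' [validate_records()]), never silently repaired.
#'
#' @param path Path to the summary CSV. `sd` and `n` may be blank.
#' @return A group-summary tibble with a `validation` attribute holding the
#'   validation-report tibble for the loaded rows.
#' @export
load_summary_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    site_scope = readr::col_character(),
    plot_class = readr::col_character(),
    medium = readr::col_character(),
    tissue = readr::col_character(),
    parameter = readr::col_character(),
    n = readr::col_integer(),
    mean = readr::col_double(),
    sd = readr::col_double(),
    min = readr::col_double(),
    max = readr::col_double()
  ), progress = FALSE)
  missing <- setdiff(setdiff(ps_summary_cols, "provenance"), names(raw))
  if (length(missing) > 0) {
    abort(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  raw$provenance <- "pre-aggregated"
  out <- raw[ps_summary_cols]
  attr(out, "validation") <- validate_records(summaries = out)
  out
}

#' Render a "mean +/- SD" display string
#'
#' Report-layer formatting only; computations always keep full precision.
#' Uses 1 decimal place (2 for values below 10), the mixed precision
#' conventional in printed biomonitoring tables.
#'
#' @param mean,sd Numeric vectors (recycled).
#' @return Character vector like `"73.6±12.7"`; `"73.6"` when `sd` is `NA`.
#' @export
format_mean_sd <- function(mean, sd = NA_real_) {
  digits <- ifelse(abs(mean) >= 10, 1L, 2L)
  m <- sprintf("%.*f", digits, mean)
  ifelse(is.na(sd), m, paste0(m, "±", sprintf("%.*f", digits, sd)))
}
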