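# Contamination factor, pollution load index, Lacatusu interval
# classification and regulatory screening. CF and PLI are the study's core
# indices:
#
#   CF_m  = C_sample(m) / C_background(m)
#   PLI   = (CF_1 * CF_2 * ... * CF_n)^(1/n)
#
# with the background taken from an uncontaminated control plot.

#' Contamination factor
#'
#' Ratio of a metal's concentration in sampled (polluted) soil to its natural
#' background concentration — here conventionally the control-plot mean. A CF
#' of 1 means no enrichment over background.
#'
#' @param c_sample Sample concentration, mg/kg (>= 0). Vectorized.
#' @param c_background Background concentration, mg/kg (> 0). Recycled.
#' @return Dimensionless CF, `c_sample / c_background`.
#' @export
contamination_factor <- function(c_sample, c_background) {
  if (any(!is.finite(c_background)) || any(c_background <= 0)) {
    abort("background must be positive")
  }
  if (any(c_sample < 0, na.rm = TRUE)) abort("sample concentration must be non-negative")
  c_sample / c_background
}

#' Pollution load index
#'
#' Geometric mean of a site's contamination factors over all measured
#' metals: `(prod(cfs))^(1/n)`. A PLI above 1 signals a net pollution load;
#' a zero CF for any metal forces the PLI to zero. Computed on the log scale
#' for numerical stability.
#'
#' @param cfs Numeric vector of contamination factors (>= 0), one per metal.
#' @return Dimensionless PLI.
#' @export
pollution_load_index <- function(cfs) {
  if (length(cfs) == 0) abort("at least one contamination factor is required")
  if (any(!is.finite(cfs)) || any(cfs < 0)) {
    abort("contamination factors must be finite and non-negative")
  }
  if (any(cfs == 0)) return(0)
  exp(mean(log(cfs)))
}

#' Per-site contamination profiles
#'
#' Builds one contamination profile per site: a CF for every metal in the
#' background set, plus the site PLI and (optionally) its pollution class.
#'
#' @param soil_values Long tibble of per-site soil metal values with columns
#'   `site_id`, `parameter`, `value` — typically per-site means or composite
#'   measurements.
#' @param background Named numeric vector of background concentrations
#'   (mg/kg), one per metal; names fix the metal set and column order.
#'   Conventionally the control-plot means (see [control_background()]).
#' @param scheme Optional classification scheme (see [lacatusu_scheme()]);
#'   when given, a `PLI_class` column is added.
#' @return A tibble with one row per site: `site_id`, `CF_<metal>` columns,
#'   `n_metals`, `PLI`, and `PLI_class` if a scheme was supplied.
#' @export
site_profiles <- function(soil_values, background, scheme = NULL) {
  if (is.null(names(background)) || any(!nzchar(names(background)))) {
    abort("background must be a named numeric vector (one value per metal)")
  }
  metals <- names(background)
  vals <- soil_values |>
    dplyr::filter(.data$parameter %in% metals)
  sites <- unique(soil_values$site_id)
  rows <- lapply(sites, function(s) {
    v <- vals[vals$site_id == s, ]
    cf <- vapply(metals, function(m) {
      x <- v$value[v$parameter == m]
      if (length(x) == 0 || all(is.na(x))) {
        abort(sprintf("site %s is missing a value for metal %s", s, m))
      }
      contamination_factor(mean(x, na.rm = TRUE), background[[m]])
    }, numeric(1))
    out <- tibble::tibble(site_id = s)
    for (m in metals) out[[paste0("CF_", m)]] <- cf[[m]]
    out$n_metals <- length(metals)
    out$PLI <- pollution_load_index(cf)
    out
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(scheme)) {
    out$PLI_class <- vapply(out$PLI, classify_index, character(1), scheme = scheme)
  }
  out
}

#' Control-plot background values from a summary table
#'
#' Convenience extractor: the per-metal control-plot soil means, in standard
#' metal order, for use as the `background` of [site_profiles()].
#'
#' @param soil_summaries A group-summary tibble covering control soil rows.
#' @param metals Metals to extract (default all five).
#' @return Named numeric vector of background concentrations (mg/kg).
#' @export
control_background <- function(soil_summaries, metals = ps_metals) {
  ctl <- soil_summaries |>
    dplyr::filter(.data$plot_class == "control", .data$medium == "soil",
                  .data$parameter %in% metals)
  missing <- setdiff(metals, ctl$parameter)
  if (length(missing) > 0) {
    abort(sprintf("no control soil mean for: %s", paste(missing, collapse = ", ")))
  }
  setNames(ctl$mean[match(metals, ctl$parameter)], metals)
}

#' The Lacatusu contamination/pollution interval scheme
#'
#' Ordered value intervals mapping a CF or PLI to a contamination class
#' (below an index of 1: "very slight" through "very severe" contamination)
#' or a pollution class (above 1: "slight" through "excessive" pollution).
#' Intervals are normalized to be contiguous with closed right endpoints
#' (see the package vignette for how the published bin edges are
#' regularized); the first interval starts at 0 and the last is unbounded.
#'
#' @return A classification-scheme tibble: `lower`, `upper`, `label`, `rank`,
#'   with a `boundary` attribute (`"closed-right"`).
#' @export
lacatusu_scheme <- function() {
  read_scheme(ps_example("lacatusu_scheme.csv"))
}

#' Read a classification scheme from CSV
#'
#' Expects columns `lower, upper, label, rank` describing ordered,
#' non-overlapping intervals that jointly cover all non-negative values
#' (`upper` blank or `Inf` on the last row). Gaps between consecutive
#' intervals are closed by extending each upper bound to the next lower
#' bound, so every non-negative value maps to exactly one label.
#'
#' @param path Path to the scheme CSV.
#' @param boundary Which side of an interior boundary belongs to the lower
#'   interval: `"closed-right"` (default; a value equal to an upper bound
#'   takes that interval's label) or `"closed-left"`.
#' @return A classification-scheme tibble ordered by `rank`.
#' @export
read_scheme <- function(path, boundary = c("closed-right", "closed-left")) {
  boundary <- match.arg(boundary)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    lower = readr::col_double(),
    upper = readr::col_double(),
    label = readr::col_character(),
    rank = readr::col_integer()
  ), progress = FALSE)
  sch <- dplyr::arrange(raw, .data$rank)
  if (sch$lower[1] != 0) abort("scheme must start at 0")
  sch$upper[is.na(sch$upper)] <- Inf
  if (nrow(sch) > 1) {
    if (any(sch$upper[-nrow(sch)] > sch$lower[-1])) {
      abort("scheme intervals overlap")
    }
    # close gaps between published bin edges (e.g. 0.25 -> 0.26): each
    # interval's upper bound is extended to the next interval's lower bound
    sch$upper[-nrow(sch)] <- sch$lower[-1]
  }
  attr(sch, "boundary") <- boundary
  sch
}

#' Classify an index value on an interval scheme
#'
#' Maps a non-negative CF or PLI to its class label under the scheme's
#' boundary convention. The same scheme object serves both individual
#' contamination factors and site PLIs.
#'
#' @param value Non-negative index value (scalar).
#' @param scheme A classification scheme from [read_scheme()] or
#'   [lacatusu_scheme()].
#' @return The class label (character scalar).
#' @export
classify_index <- function(value, scheme = lacatusu_scheme()) {
  if (!is.finite(value) || value < 0) abort("index value must be non-negative")
  boundary <- attr(scheme, "boundary") %||% "closed-right"
  hit <- if (boundary == "closed-right") {
    which((value > scheme$lower | (value == 0 & scheme$lower == 0)) &
            value <= scheme$upper)
  } else {
    which(value >= scheme$lower & value < scheme$upper)
  }
  if (length(hit) == 0) abort(sprintf("value %g is outside the scheme's support", value))
  scheme$label[hit[1]]
}

#' Screen summary means against regulatory limits
#'
#' Compares each group-summary mean with every applicable regulatory limit
#' (matched on medium and parameter). Verdicts: `"exceeds"` when the mean is
#' above the upper limit, `"below"` when it is under the lower limit, and
#' `"within-range"` inside a ranged limit. Parameters with no matching limit
#' are skipped and listed in the `skipped` attribute.
#'
#' @param summaries A group-summary tibble.
#' @param limits A regulatory-limit tibble from [read_limits()].
#' @return An exceedance-report tibble: `plot_class`, `medium`, `tissue`,
#'   `parameter`, `authority`, `observed`, `limit_low`, `limit_high`,
#'   `verdict`; unmatched (medium, parameter) pairs in `attr(, "skipped")`.
#' @export
screen_against_limits <- function(summaries, limits) {
  joined <- dplyr::inner_join(
    summaries, limits,
    by = c("medium", "parameter"), relationship = "many-to-many"
  )
  skipped <- summaries |>
    dplyr::anti_join(limits, by = c("medium", "parameter")) |>
    dplyr::distinct(.data$medium, .data$parameter)
  out <- joined |>
    dplyr::transmute(
      plot_class = .data$plot_class,
      medium = .data$medium,
      tissue = .data$tissue,
      parameter = .data$parameter,
      authority = .data$authority,
      observed = .data$mean,
      limit_low = .data$limit_low,
      limit_high = .data$limit_high,
      verdict = dplyr::case_when(
        .data$mean > .data$limit_high ~ "exceeds",
        .data$mean < .data$limit_low ~ "below",
        TRUE ~ "within-range"
      )
    )
  attr(out, "skipped") <- skipped
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
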