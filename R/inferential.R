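# Inferential screening: paired t-tests (test vs control series matched by
# site) and Pearson correlation between soil and tissue parameters across
# sites. Both wrap the stats:: implementations; the degenerate zero-variance
# cases a pipeline must survive are handled explicitly because t.test()
# raises them as errors.

#' Paired t-test between two matched series
#'
#' Tests the mean of the paired differences `d = x - y` against zero:
#' `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees of freedom, two
#' sided. Pairing is by position (site order). Degenerate inputs are
#' resolved rather than raised: all-zero differences give `t = 0, p = 1`;
#' constant nonzero differences give an infinite `t` with `p = 0`.
#'
#' @param x,y Equal-length numeric series (n >= 2), paired by position.
#' @return A one-row tibble: `t`, `df`, `p`, `n`, `mean_difference`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 2) abort("at least two pairs are required")
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported")
  d <- x - y
  md <- mean(d)
  if (stats::sd(d) == 0) {
    t_stat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    fit <- stats::t.test(x, y, paired = TRUE)
    t_stat <- unname(fit$statistic)
    p <- fit$p.value
  }
  tibble::tibble(t = t_stat, df = n - 1L, p = p, n = n, mean_difference = md)
}

#' Pearson correlation with significance flag
#'
#' Standard product-moment correlation with a two-sided p-value from the
#' t transform on `n - 2` degrees of freedom, flagged at the configured
#' significance level.
#'
#' @param x,y Equal-length numeric series (n >= 3), both non-constant.
#' @param alpha Significance level for the flag (default 0.05).
#' @return A one-row tibble: `r`, `n`, `p`, `significant`.
#' @export
pearson_r <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 3) abort("at least three pairs are required")
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined for a constant series")
  }
  fit <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(
    r = unname(fit$estimate),
    n = n,
    p = fit$p.value,
    significant = fit$p.value < alpha
  )
}

#' Soil-tissue correlation matrix across sites
#'
#' Correlates every (tissue, parameter) series with every soil parameter
#' series across sites — the layout of a soil-plant relationship table:
#' rows are tissue parameters (parameter x tissue), columns are soil
#' parameters. Site-level values are the means over replicates.
#'
#' @param records A concentration-record tibble covering >= 3 sites with
#'   both soil and tissue measurements.
#' @param alpha Significance level for the flags (default 0.05).
#' @param adjust P-value adjustment: `"none"` (default, matching common
#'   field practice) or `"holm"`.
#' @return A tibble with one row per (tissue parameter, soil parameter)
#'   pair: `tissue_parameter`, `tissue`, `soil_parameter`, `r`, `n`, `p`,
#'   `significant`.
#' @export
soil_tissue_correlation_matrix <- function(records, alpha = 0.05,
                                           adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  site_means <- records |>
    dplyr::group_by(.data$site_id, .data$medium, .data$tissue, .data$parameter) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  soil <- dplyr::filter(site_means, .data$medium == "soil")
  tiss <- dplyr::filter(site_means, .data$medium == "tissue")
  sites <- sort(intersect(unique(soil$site_id), unique(tiss$site_id)))
  if (length(sites) < 3) abort("fewer than 3 complete sites")

  series <- function(df, param, tis = NULL) {
    sel <- df$parameter == param
    if (!is.null(tis)) sel <- sel & df$tissue == tis
    v <- df[sel, ]
    v$value[match(sites, v$site_id)]
  }
  soil_params <- intersect(ps_parameters, unique(soil$parameter))
  tissue_keys <- tiss |>
    dplyr::distinct(.data$parameter, .data$tissue) |>
    dplyr::arrange(match(.data$parameter, ps_parameters),
                   match(.data$tissue, ps_tissues))

  grid <- tidyr::expand_grid(
    row = seq_len(nrow(tissue_keys)),
    soil_parameter = soil_params
  )
  out <- purrr::pmap_dfr(grid, function(row, soil_parameter) {
    tp <- tissue_keys$parameter[row]
    tt <- tissue_keys$tissue[row]
    xs <- series(tiss, tp, tt)
    ys <- series(soil, soil_parameter)
    if (anyNA(xs) || anyNA(ys)) {
      abort(sprintf("incomplete site coverage for %s %s vs soil %s", tt, tp, soil_parameter))
    }
    res <- pearson_r(xs, ys, alpha = alpha)
    tibble::tibble(
      tissue_parameter = tp, tissue = tt, soil_parameter = soil_parameter,
      r = res$r, n = res$n, p = res$p
    )
  })
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, method = "holm")
  out$significant <- out$p < alpha
  out
}
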