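# Plant accumulation metrics. The aerial portion is the above-ground tissue
# pool (leaf + fruit + stem mean concentrations); the translocation factor
# divides it by the root concentration; the plant/soil ratio divides the mean
# of the four tissue means by the supporting-soil concentration.

#' Aerial-portion concentration
#'
#' Sum of the leaf, fruit and stem mean concentrations: the above-ground
#' metal pool used as the translocation-factor numerator.
#'
#' @param leaf,fruit,stem Tissue mean concentrations, mg/kg (>= 0).
#'   Vectorized.
#' @return Aerial-portion concentration, mg/kg.
#' @export
aerial_concentration <- function(leaf, fruit, stem) {
  if (any(c(leaf, fruit, stem) < 0, na.rm = TRUE)) {
    abort("tissue concentrations must be non-negative")
  }
  leaf + fruit + stem
}

#' Translocation factor
#'
#' Ratio of the aerial-portion concentration to the root concentration. A TF
#' above 1 indicates efficient root-to-shoot movement — the trait that makes
#' a species a phytoextraction candidate.
#'
#' @param aerial Aerial-portion concentration, mg/kg (>= 0). Vectorized.
#' @param root Root concentration, mg/kg (> 0). Recycled.
#' @return Dimensionless TF, `aerial / root`.
#' @export
translocation_factor <- function(aerial, root) {
  if (any(root <= 0, na.rm = TRUE)) abort("root concentration must be positive")
  if (any(aerial < 0, na.rm = TRUE)) abort("aerial concentration must be non-negative")
  aerial / root
}

#' Plant/soil metal concentration ratio
#'
#' Arithmetic mean of the four tissue concentrations (root, leaf, fruit,
#' stem) divided by the supporting-soil concentration: a whole-plant
#' bioaccumulation indicator.
#'
#' @param root,leaf,fruit,stem Tissue concentrations, mg/kg (>= 0).
#'   Vectorized.
#' @param soil Soil concentration, mg/kg (> 0). Recycled.
#' @return Dimensionless ratio, `mean(tissues) / soil`.
#' @export
plant_soil_ratio <- function(root, leaf, fruit, stem, soil) {
  if (any(soil <= 0, na.rm = TRUE)) abort("soil concentration must be positive")
  if (any(c(root, leaf, fruit, stem) < 0, na.rm = TRUE)) {
    abort("tissue concentrations must be non-negative")
  }
  (root + leaf + fruit + stem) / 4 / soil
}

#' Accumulation table: aerial portion, TF and plant/soil ratio per metal
#'
#' Combines per-tissue and soil summary means into one accumulation result
#' per (metal, plot class): aerial portion, root value, translocation
#' factor, whole-plant mean, soil mean, and plant/soil ratio. Input metal
#' order is preserved.
#'
#' @param tissue_summaries Group-summary tibble with the four tissue means
#'   per metal and plot class (`medium == "tissue"`).
#' @param soil_summaries Group-summary tibble with soil means per metal and
#'   plot class (`medium == "soil"`).
#' @param metals Metals to tabulate; defaults to the metals present in
#'   `tissue_summaries`, in order of first appearance.
#' @return A tibble with columns `metal`, `plot_class`, `aerial`, `root`,
#'   `TF`, `plant_mean`, `soil_mean`, `ratio`.
#' @export
accumulation_table <- function(tissue_summaries, soil_summaries, metals = NULL) {
  tis <- dplyr::filter(tissue_summaries, .data$medium == "tissue",
                       .data$parameter %in% ps_metals)
  soi <- dplyr::filter(soil_summaries, .data$medium == "soil",
                       .data$parameter %in% ps_metals)
  if (is.null(metals)) metals <- unique(tis$parameter)
  classes <- intersect(ps_plot_classes, unique(tis$plot_class))
  rows <- list()
  for (pc in classes) {
    for (m in metals) {
      cell <- function(t) {
        x <- tis$mean[tis$plot_class == pc & tis$parameter == m & tis$tissue == t]
        if (length(x) != 1 || is.na(x)) {
          abort(sprintf("missing %s mean for metal %s (%s plots)", t, m, pc))
        }
        x
      }
      root <- cell("root"); leaf <- cell("leaf")
      fruit <- cell("fruit"); stem <- cell("stem")
      s <- soi$mean[soi$plot_class == pc & soi$parameter == m]
      if (length(s) != 1 || is.na(s)) {
        abort(sprintf("missing soil mean for metal %s (%s plots)", m, pc))
      }
      aerial <- aerial_concentration(leaf, fruit, stem)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metal = m,
        plot_class = pc,
        aerial = aerial,
        root = root,
        TF = translocation_factor(aerial, root),
        plant_mean = (root + leaf + fruit + stem) / 4,
        soil_mean = s,
        ratio = plant_soil_ratio(root, leaf, fruit, stem, s)
      )
    }
  }
  dplyr::bind_rows(rows)
}
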