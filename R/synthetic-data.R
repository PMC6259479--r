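# Seeded synthetic-data generator: emulates a multi-site biomonitoring
# survey (polluted sites enriched over a control baseline, positive
# soil -> tissue transfer) with closed-form ground truth, so every pipeline
# stage can be validated without field data.
#
# Concentration model, per metal m:
#   soil(site, stand)   = median_m * enrichment_m(site) * exp(sigma_s * Z)
#   tissue(t, stand)    = soil * slope_m * w_t * exp(sigma_n * Z - sigma_n^2/2)
# Soil is median-parameterized (changing sigma_s leaves the median fixed);
# tissue noise is mean-one lognormal so expected tissue/soil ratios equal
# slope_m * w_t with no correction term.

#' Construct a synthetic study design
#'
#' Defaults emulate a seven-workshop survey with one control plot, three
#' plant stands per site, and five metals whose control baselines,
#' enrichment factors and soil-to-plant transfer slopes are set to the
#' magnitudes typical of automobile-workshop contamination (test-plot soil
#' Pb around 74 mg/kg, strong Zn/Cu enrichment, whole-plant/soil ratios
#' between 0.48 and 0.78).
#'
#' @param n_test_sites Number of polluted sites (default 7); one control
#'   site is always added.
#' @param n_stands_per_site Plant stands (replicates) per site (default 3).
#' @param metals Metal names.
#' @param control_soil_median Named per-metal control soil medians, mg/kg.
#' @param enrichment Named per-metal multiplicative enrichment of test-site
#'   soil over the control baseline (1 = unpolluted).
#' @param transfer_slope Named per-metal expected whole-plant-mean / soil
#'   concentration ratio.
#' @param tissue_partition Relative weights for root/leaf/fruit/stem
#'   averaging 1 (summing to 4), partitioning plant uptake across tissues.
#' @param lognormal_sigma Log-scale dispersion of soil concentrations
#'   (default 0.3, giving a soil CV of about 31%).
#' @param noise_sigma Log-scale residual dispersion of tissue values around
#'   their soil-driven expectation (default 0.15).
#' @param ph_soil,ph_tissue Length-2 vectors `c(test, control)` of mean pH.
#' @param ec_soil,ec_tissue Length-2 vectors `c(test, control)` of median
#'   EC, uS/cm.
#' @param seed Integer seed; generation is deterministic given the design.
#' @return A `ps_design` list of the validated fields.
#' @export
study_design <- function(n_test_sites = 7,
                         n_stands_per_site = 3,
                         metals = ps_metals,
                         control_soil_median = c(Pb = 21.9, Hg = 17.1, Cd = 4.7,
                                                 Cu = 5.4, Zn = 3.2),
                         enrichment = c(Pb = 3.4, Hg = 2.2, Cd = 4.3,
                                        Cu = 10.4, Zn = 14.9),
                         transfer_slope = c(Pb = 0.61, Hg = 0.78, Cd = 0.61,
                                            Cu = 0.69, Zn = 0.48),
                         tissue_partition = c(root = 1.1, leaf = 1.0,
                                              fruit = 0.95, stem = 0.95),
                         lognormal_sigma = 0.3,
                         noise_sigma = 0.15,
                         ph_soil = c(test = 4.7, control = 6.6),
                         ph_tissue = c(test = 5.7, control = 8.1),
                         ec_soil = c(test = 1660, control = 420),
                         ec_tissue = c(test = 1450, control = 400),
                         seed = 1L) {
  design <- list(
    n_test_sites = n_test_sites, n_stands_per_site = n_stands_per_site,
    metals = metals, control_soil_median = control_soil_median,
    enrichment = enrichment, transfer_slope = transfer_slope,
    tissue_partition = tissue_partition,
    lognormal_sigma = lognormal_sigma, noise_sigma = noise_sigma,
    ph_soil = ph_soil, ph_tissue = ph_tissue,
    ec_soil = ec_soil, ec_tissue = ec_tissue, seed = as.integer(seed)
  )
  validate_design(design)
  structure(design, class = "ps_design")
}

validate_design <- function(d) {
  fail <- function(field, why) abort(sprintf("invalid design field '%s': %s", field, why))
  if (!is.numeric(d$n_test_sites) || d$n_test_sites < 1) {
    fail("n_test_sites", "must be >= 1")
  }
  if (!is.numeric(d$n_stands_per_site) || d$n_stands_per_site < 1) {
    fail("n_stands_per_site", "must be >= 1")
  }
  for (field in c("control_soil_median", "enrichment", "transfer_slope")) {
    v <- d[[field]]
    if (!all(d$metals %in% names(v))) fail(field, "needs a value for every metal")
    if (any(v[d$metals] <= 0)) fail(field, "values must be positive")
  }
  w <- d$tissue_partition
  if (!all(ps_tissues %in% names(w))) fail("tissue_partition", "needs root/leaf/fruit/stem")
  if (any(w <= 0)) fail("tissue_partition", "weights must be positive")
  if (abs(mean(w[ps_tissues]) - 1) > 1e-8) {
    fail("tissue_partition", "weights must average 1 (sum to 4)")
  }
  if (d$lognormal_sigma < 0) fail("lognormal_sigma", "must be >= 0")
  if (d$noise_sigma < 0) fail("noise_sigma", "must be >= 0")
  invisible(d)
}

#' Generate a synthetic biomonitoring dataset
#'
#' Draws a full study: per-stand soil metal values lognormally distributed
#' around `control_soil_median * enrichment` (enrichment 1 at the control
#' site), tissue values driven by the stand's soil value through the
#' transfer slope and tissue partition with mean-one lognormal residuals,
#' plus pH (normal, sd 0.4) and EC (lognormal, sigma 0.25) series with the
#' configured test/control offsets. Deterministic given the design seed.
#'
#' @param design A `ps_design` from [study_design()].
#' @return A concentration-record tibble (test sites `"S1"`... plus
#'   `"control"`).
#' @export
generate_study <- function(design) {
  validate_design(design)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(design$seed)

  sites <- c(paste0("S", seq_len(design$n_test_sites)), "control")
  classes <- c(rep("test", design$n_test_sites), "control")
  n_stand <- design$n_stands_per_site
  metals <- design$metals
  sig_s <- design$lognormal_sigma
  sig_n <- design$noise_sigma
  w <- design$tissue_partition[ps_tissues]

  # soil metal grid: site x stand x metal (vectorized draws)
  grid <- tidyr::expand_grid(
    site_idx = seq_along(sites), replicate = seq_len(n_stand), parameter = metals
  )
  enr <- ifelse(classes[grid$site_idx] == "test",
                design$enrichment[grid$parameter], 1)
  soil_val <- design$control_soil_median[grid$parameter] * enr *
    exp(sig_s * rnorm(nrow(grid)))
  soil_metals <- tibble::tibble(
    site_id = sites[grid$site_idx], plot_class = classes[grid$site_idx],
    medium = "soil", tissue = "none", parameter = grid$parameter,
    replicate = grid$replicate, value = unname(soil_val)
  )

  # tissues driven by the same stand's soil value; mean-one lognormal noise
  tgrid <- tidyr::expand_grid(row = seq_len(nrow(grid)), tissue = ps_tissues)
  noise <- exp(sig_n * rnorm(nrow(tgrid)) - sig_n^2 / 2)
  tval <- soil_val[tgrid$row] * design$transfer_slope[grid$parameter[tgrid$row]] *
    w[tgrid$tissue] * noise
  tissue_metals <- tibble::tibble(
    site_id = soil_metals$site_id[tgrid$row],
    plot_class = soil_metals$plot_class[tgrid$row],
    medium = "tissue", tissue = tgrid$tissue,
    parameter = soil_metals$parameter[tgrid$row],
    replicate = soil_metals$replicate[tgrid$row], value = unname(tval)
  )

  # pH and EC series with configured test/control offsets
  sgrid <- tidyr::expand_grid(site_idx = seq_along(sites), replicate = seq_len(n_stand))
  spc <- classes[sgrid$site_idx]
  ph_s <- pmin(pmax(design$ph_soil[spc] + rnorm(nrow(sgrid), sd = 0.4), 0), 14)
  ec_s <- design$ec_soil[spc] * exp(0.25 * rnorm(nrow(sgrid)))
  soil_phys <- tibble::tibble(
    site_id = rep(sites[sgrid$site_idx], 2), plot_class = rep(spc, 2),
    medium = "soil", tissue = "none",
    parameter = rep(c("pH", "EC"), each = nrow(sgrid)),
    replicate = rep(sgrid$replicate, 2), value = c(unname(ph_s), unname(ec_s))
  )
  pgrid <- tidyr::expand_grid(row = seq_len(nrow(sgrid)), tissue = ps_tissues)
  ppc <- spc[pgrid$row]
  ph_t <- pmin(pmax(design$ph_tissue[ppc] + rnorm(nrow(pgrid), sd = 0.4), 0), 14)
  ec_t <- design$ec_tissue[ppc] * exp(0.25 * rnorm(nrow(pgrid)))
  tissue_phys <- tibble::tibble(
    site_id = rep(sites[sgrid$site_idx[pgrid$row]], 2), plot_class = rep(ppc, 2),
    medium = "tissue", tissue = rep(pgrid$tissue, 2),
    parameter = rep(c("pH", "EC"), each = nrow(pgrid)),
    replicate = rep(sgrid$replicate[pgrid$row], 2),
    value = c(unname(ph_t), unname(ec_t))
  )

  dplyr::bind_rows(soil_metals, tissue_metals, soil_phys, tissue_phys)
}

#' Closed-form ground truth implied by a design
#'
#' The expectations the generator's parameters imply for each pipeline
#' output, per metal: contamination factor = enrichment (soil dispersion
#' affects sample and background identically, so the median-lognormal mean
#' factors cancel); translocation factor = (w_leaf + w_fruit + w_stem) /
#' w_root; plant/soil ratio = transfer slope (tissue noise is mean-one by
#' construction).
#'
#' @param design A `ps_design` from [study_design()].
#' @return A tibble with columns `metal`, `cf`, `tf`, `ratio`.
#' @export
ground_truth <- function(design) {
  validate_design(design)
  w <- design$tissue_partition
  tf <- (w[["leaf"]] + w[["fruit"]] + w[["stem"]]) / w[["root"]]
  tibble::tibble(
    metal = design$metals,
    cf = unname(design$enrichment[design$metals]),
    tf = tf,
    ratio = unname(design$transfer_slope[design$metals])
  )
}

# Save/restore the global RNG state so generation is a pure function of the
# design seed without clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
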