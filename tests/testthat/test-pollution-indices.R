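test_that("contamination factor is the sample/background ratio with guards", {
  expect_equal(contamination_factor(21.9, 21.9), 1.0)
  expect_equal(contamination_factor(73.6, 21.9), 3.361, tolerance = 5e-4)
  expect_equal(contamination_factor(0, 21.9), 0)
  expect_error(contamination_factor(5, 0), "background must be positive")
  expect_error(contamination_factor(-1, 2), "non-negative")

  # homogeneity: common rescaling cancels
  set.seed(3)
  for (i in 1:20) {
    a <- stats::runif(1, 0, 100); b <- stats::runif(1, 0.1, 50)
    k <- stats::runif(1, 0.01, 10)
    expect_equal(contamination_factor(k * a, k * b),
                 contamination_factor(a, b), tolerance = 1e-12)
  }
})

test_that("PLI is the geometric mean of the contamination factors", {
  s1 <- c(2.9, 1.7, 2.0, 5.1, 9.2)
  expect_equal(round(pollution_load_index(s1), 1), 3.4)
  expect_equal(pollution_load_index(rep(1, 5)), 1.0)
  # brute-force product-then-root oracle
  s7 <- c(3.6, 2.1, 9.4, 17.9, 32.5)
  expect_equal(pollution_load_index(s7), prod(s7)^(1 / 5), tolerance = 1e-12)
  expect_equal(pollution_load_index(s7), 8.3806, tolerance = 1e-4)
  expect_equal(pollution_load_index(c(2, 0, 3)), 0)
  expect_error(pollution_load_index(numeric(0)), "at least one")
})

test_that("PLI properties: equality, scaling, permutation, bounds", {
  set.seed(17)
  for (i in 1:25) {
    cfs <- stats::rlnorm(sample(2:8, 1), sdlog = 1)
    k <- stats::runif(1, 0.1, 10)
    p <- pollution_load_index(cfs)
    expect_equal(pollution_load_index(rep(cfs[1], 5)), cfs[1], tolerance = 1e-12)
    expect_equal(pollution_load_index(k * cfs), k * p, tolerance = 1e-10)
    expect_equal(pollution_load_index(sample(cfs)), p, tolerance = 1e-12)
    expect_gte(p, min(cfs) - 1e-12)
    expect_lte(p, max(cfs) + 1e-12)
  }
})

test_that("site profiles rebuild per-site CFs and PLIs from soil values", {
  # soil values constructed as cf * background recover the CF matrix exactly
  cfm <- cf_matrix()
  background <- control_background(soil_summaries())
  soil_values <- dplyr::bind_rows(lapply(names(cfm), function(s) {
    tibble::tibble(site_id = s, parameter = names(cfm[[s]]),
                   value = unname(cfm[[s]]) * background[names(cfm[[s]])])
  }))
  prof <- site_profiles(soil_values, background, scheme = lacatusu_scheme())
  expect_equal(nrow(prof), 7L)
  expect_equal(prof$n_metals, rep(5L, 7))
  expect_equal(prof$CF_Zn[prof$site_id == "S1"], 9.2, tolerance = 1e-12)
  expect_equal(prof$PLI[prof$site_id == "S4"],
               prod(cfm$S4)^(1 / 5), tolerance = 1e-12)
  expect_equal(prof$PLI_class[prof$site_id == "S1"], "Moderate pollution")
  expect_equal(prof$PLI_class[prof$site_id == "S5"], "Severe pollution")

  expect_equal(site_profiles(
    tibble::tibble(site_id = "X", parameter = names(background), value = 2 * background),
    background
  )$PLI, 2, tolerance = 1e-12)

  expect_error(
    site_profiles(dplyr::filter(soil_values, parameter != "Zn"), background),
    "S1.*Zn"
  )
})

test_that("Lacatusu classification maps index values through normalized intervals", {
  sch <- lacatusu_scheme()
  expect_equal(classify_index(3.4, sch), "Moderate pollution")
  expect_equal(classify_index(7.6, sch), "Severe pollution")
  expect_equal(classify_index(0.05, sch), "Very slight contamination")
  expect_equal(classify_index(0, sch), "Very slight contamination")
  expect_equal(classify_index(8.3, sch), "Severe pollution")  # table beats prose
  expect_equal(classify_index(1000, sch), "Excessive pollution")
  expect_error(classify_index(-0.1, sch), "non-negative")

  # monotone: larger values never map to a lower rank
  set.seed(5)
  v <- sort(stats::runif(100, 0, 40))
  ranks <- sch$rank[match(vapply(v, classify_index, character(1), scheme = sch),
                          sch$label)]
  expect_true(all(diff(ranks) >= 0))

  # every non-negative value maps to exactly one label (contiguity)
  edges <- c(0, 0.1, 0.25, 0.26, 1.0, 1.1, 2.0, 2.1, 4.0, 4.1, 9.05, 16.0, 16.5)
  expect_true(all(nzchar(vapply(edges, classify_index, character(1), scheme = sch))))
})

test_that("regulatory screening issues verdicts per matched limit", {
  lim <- read_limits(fixture_path("regulatory_limits.csv"))
  rep <- screen_against_limits(
    dplyr::bind_rows(soil_summaries(), tissue_summaries()), lim
  )
  verdict <- function(pc, med, par, auth, tis = NULL) {
    r <- dplyr::filter(rep, plot_class == pc, medium == med,
                       parameter == par, authority == auth)
    if (!is.null(tis)) r <- dplyr::filter(r, tissue == tis)
    unique(r$verdict)
  }
  expect_equal(verdict("test", "soil", "Hg", "DPR"), "exceeds")   # 38.4 vs 0.3
  expect_equal(verdict("test", "soil", "Pb", "USEPA"), "below")   # 73.6 vs 300
  expect_equal(verdict("test", "tissue", "Hg", "WHO", "leaf"), "exceeds")  # 32.0 vs 0.05-0.5

  # within-range verdict inside a ranged limit
  mid <- tibble::tibble(
    site_scope = "all", plot_class = "test", medium = "tissue", tissue = "leaf",
    parameter = "Hg", n = 7L, mean = 0.3, sd = NA_real_, min = 0.1, max = 0.5,
    provenance = "computed"
  )
  expect_equal(screen_against_limits(mid, lim)$verdict, "within-range")

  # unmatched parameters are skipped and listed
  skipped <- attr(rep, "skipped")
  expect_true(all(c("pH", "EC") %in% skipped$parameter))
  expect_false(any(rep$parameter %in% c("pH", "EC")))
})
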