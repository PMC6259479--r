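test_that("generation is deterministic given the seed and leaves the RNG alone", {
  d <- study_design(seed = 99)
  r1 <- generate_study(d)
  set.seed(1)
  before <- rnorm(1)
  r2 <- generate_study(d)
  set.seed(1)
  expect_equal(rnorm(1), before)  # caller RNG stream unperturbed
  expect_equal(r1, r2)
  expect_false(identical(r1, generate_study(study_design(seed = 100))))
})

test_that("the default design emulates the stated survey shape", {
  rec <- generate_study(study_design(seed = 1))
  expect_equal(length(unique(rec$site_id)), 8L)  # 7 test + control
  expect_equal(sort(unique(rec$plot_class)), c("control", "test"))
  expect_equal(max(rec$replicate), 3L)
  expect_equal(sort(unique(rec$parameter)), sort(c("pH", "EC", "Pb", "Hg", "Cd", "Cu", "Zn")))
  expect_equal(nrow(validate_records(rec)), 0L)  # generated data is clean

  # magnitudes resemble a workshop survey (smoke only): test soil Pb ~ 74
  pb <- dplyr::filter(rec, medium == "soil", parameter == "Pb", plot_class == "test")
  expect_gt(mean(pb$value), 30)
  expect_lt(mean(pb$value), 150)
})

test_that("zero dispersion collapses to the design medians exactly", {
  d <- study_design(lognormal_sigma = 0, noise_sigma = 0, seed = 5)
  rec <- generate_study(d)
  soil <- dplyr::filter(rec, medium == "soil", parameter %in% c("Pb", "Hg", "Cd", "Cu", "Zn"))
  expected <- ifelse(
    soil$plot_class == "test",
    d$control_soil_median[soil$parameter] * d$enrichment[soil$parameter],
    d$control_soil_median[soil$parameter]
  )
  expect_equal(soil$value, unname(expected), tolerance = 1e-12)

  # tissues then sit exactly at soil * slope * weight
  root_pb <- dplyr::filter(rec, medium == "tissue", tissue == "root",
                           parameter == "Pb", plot_class == "test")
  expect_equal(root_pb$value,
               rep(d$control_soil_median[["Pb"]] * d$enrichment[["Pb"]] *
                     d$transfer_slope[["Pb"]] * d$tissue_partition[["root"]],
                   nrow(root_pb)),
               tolerance = 1e-12)
})

test_that("ground truth encodes the closed-form design expectations", {
  d <- study_design()
  gt <- ground_truth(d)
  expect_equal(gt$cf, unname(d$enrichment[gt$metal]))
  expect_equal(gt$ratio, unname(d$transfer_slope[gt$metal]))

  d2 <- study_design(tissue_partition = c(root = 1, leaf = 1, fruit = 1, stem = 1))
  expect_equal(unique(ground_truth(d2)$tf), 3.0)
  d3 <- study_design(tissue_partition = c(root = 0.8, leaf = 1.2, fruit = 1.1, stem = 0.9))
  expect_equal(unique(ground_truth(d3)$tf), (1.2 + 1.1 + 0.9) / 0.8)  # = 4
  d4 <- study_design(transfer_slope = c(Pb = 0.776, Hg = 0.776, Cd = 0.776,
                                        Cu = 0.776, Zn = 0.776))
  expect_equal(unique(ground_truth(d4)$ratio), 0.776)
})

test_that("invalid designs are rejected naming the offending field", {
  expect_error(study_design(n_test_sites = 0), "n_test_sites")
  expect_error(study_design(enrichment = c(Pb = -1, Hg = 2, Cd = 2, Cu = 2, Zn = 2)),
               "enrichment")
  expect_error(study_design(tissue_partition = c(root = 2, leaf = 2, fruit = 2, stem = 2)),
               "tissue_partition")
  expect_error(study_design(lognormal_sigma = -0.1), "lognormal_sigma")
  expect_error(study_design(transfer_slope = c(Pb = 0.5)), "transfer_slope")
})

test_that("known-background mean CF concentrates on the enrichment at large n", {
  # 200 test sites, sigma 0.3; site CFs against the design's true background
  # median. Soil is median-parameterized, so arithmetic site means carry the
  # lognormal mean factor exp(sigma^2 / 2); apply it to the target.
  d <- study_design(n_test_sites = 200, seed = 42,
                    enrichment = c(Pb = 3.4, Hg = 2.2, Cd = 4.3, Cu = 10.4, Zn = 14.9))
  rec <- generate_study(d)
  site_pb <- rec |>
    dplyr::filter(plot_class == "test", medium == "soil", parameter == "Pb") |>
    dplyr::group_by(site_id) |>
    dplyr::summarise(value = mean(value), .groups = "drop")
  cfs <- contamination_factor(site_pb$value, d$control_soil_median[["Pb"]])
  expect_lt(abs(mean(cfs) - 3.4 * exp(d$lognormal_sigma^2 / 2)), 0.15)
})

test_that("unenriched designs classify nearly all sites at background levels", {
  d <- study_design(
    n_test_sites = 100,
    enrichment = c(Pb = 1, Hg = 1, Cd = 1, Cu = 1, Zn = 1),
    lognormal_sigma = 0.2, seed = 7
  )
  rec <- generate_study(d)
  site_soil <- rec |>
    dplyr::filter(medium == "soil", parameter %in% c("Pb", "Hg", "Cd", "Cu", "Zn")) |>
    dplyr::group_by(site_id, plot_class, parameter) |>
    dplyr::summarise(value = mean(value), .groups = "drop")
  background <- site_soil |>
    dplyr::filter(plot_class == "control") |>
    (\(x) setNames(x$value, x$parameter))()
  prof <- site_profiles(dplyr::filter(site_soil, plot_class == "test"),
                        background, scheme = lacatusu_scheme())
  sch <- lacatusu_scheme()
  slight_rank <- sch$rank[sch$label == "Slight pollution"]
  ranks <- sch$rank[match(prof$PLI_class, sch$label)]
  expect_gte(mean(ranks <= slight_rank), 0.95)
})
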