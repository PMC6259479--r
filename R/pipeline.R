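# End-to-end orchestration from a flat key=value config file. Each stage
# mirrors one report table: grouped summaries, per-site contamination
# profiles, the accumulation table, the soil-tissue correlation matrix, and
# the regulatory exceedance report, plus a machine-readable run manifest.

#' Read a flat key=value (or key: value) config file
#'
#' Blank lines and `#` comments are ignored; values are returned as strings.
#'
#' @param path Path to the config file.
#' @return A named list of character values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3]
  if (length(bad) > 0) abort(sprintf("unparseable config line: '%s'", bad[1]))
  out <- lapply(kv, function(m) trimws(m[3]))
  names(out) <- vapply(kv, function(m) trimws(m[2]), character(1))
  out
}

#' Run the full biomonitoring pipeline from a config file
#'
#' Reads (or simulates) concentration records, then writes the standard
#' report tables to the output directory: `summary.csv` (grouped
#' descriptives), `profiles.csv` (per-site contamination factors + PLI +
#' class), `accumulation.csv` (aerial portion / TF / plant-soil ratio per
#' metal), `correlation.csv` (soil-tissue correlation matrix),
#' `exceedance.csv` (regulatory screening), and `manifest.json` (inputs,
#' config hash, package version, seed). All randomness flows through the
#' single seed recorded in the manifest; two runs with identical config and
#' seed produce byte-identical CSVs. Inputs are checked before any output
#' is written; on failure a `FAILED` marker is left next to any partial
#' outputs.
#'
#' Config keys: `records` (long CSV path) or `simulate: true` (+ optional
#' `n_test_sites`, `sigma`); `limits` and `scheme` (CSV paths, default the
#' bundled WHO/DPR/USEPA and Lacatusu tables); `out_dir`; `seed`; `alpha`.
#'
#' @param config Path to a flat key=value config file.
#' @param out_dir Output directory, overriding the config's `out_dir`.
#' @param seed Integer seed, overriding the config's `seed`.
#' @return Invisibly, a named list of the written file paths.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- read_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% abort("config must name an out_dir")
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  alpha <- as.numeric(cfg$alpha %||% 0.05)
  simulate <- tolower(cfg$simulate %||% "false") %in% c("true", "yes", "1")

  limits_path <- cfg$limits %||% ps_example("regulatory_limits.csv")
  scheme_path <- cfg$scheme %||% ps_example("lacatusu_scheme.csv")
  # validate every input before writing anything
  if (!file.exists(limits_path)) abort(sprintf("limits file not found: %s", limits_path))
  if (!file.exists(scheme_path)) abort(sprintf("scheme file not found: %s", scheme_path))
  if (!simulate) {
    if (is.null(cfg$records)) abort("config must name a records file or set simulate: true")
    if (!file.exists(cfg$records)) {
      abort(sprintf("records file not found: %s", cfg$records))
    }
  }
  limits <- read_limits(limits_path)
  scheme <- read_scheme(scheme_path)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, "FAILED")
  if (file.exists(marker)) file.remove(marker)
  done <- FALSE
  on.exit({
    if (!done) writeLines("pipeline did not complete", marker)
  }, add = TRUE)

  if (simulate) {
    design <- study_design(
      n_test_sites = as.integer(cfg$n_test_sites %||% 7L),
      lognormal_sigma = as.numeric(cfg$sigma %||% 0.3),
      seed = seed
    )
    records <- generate_study(design)
    records_input <- "simulated"
  } else {
    records <- read_concentration_table(cfg$records)
    records_input <- cfg$records
  }
  report <- validate_records(records)
  if (any(report$severity == "error")) {
    abort(sprintf(
      "records failed validation (%d error(s)); first: %s",
      sum(report$severity == "error"), report$message[report$severity == "error"][1]
    ))
  }

  summaries <- summarize_concentrations(records)
  site_soil <- records |>
    dplyr::filter(.data$medium == "soil", .data$parameter %in% ps_metals) |>
    dplyr::group_by(.data$site_id, .data$plot_class, .data$parameter) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  background <- site_soil |>
    dplyr::filter(.data$plot_class == "control") |>
    (\(d) setNames(d$value[match(ps_metals, d$parameter)], ps_metals))()
  if (anyNA(background)) abort("control-plot soil values are required for backgrounds")
  profiles <- site_profiles(
    dplyr::filter(site_soil, .data$plot_class == "test"),
    background, scheme = scheme
  )
  accumulation <- accumulation_table(summaries, summaries)
  correlation <- soil_tissue_correlation_matrix(records, alpha = alpha)
  exceedance <- screen_against_limits(summaries, limits)

  paths <- list(
    summary = file.path(out_dir, "summary.csv"),
    profiles = file.path(out_dir, "profiles.csv"),
    accumulation = file.path(out_dir, "accumulation.csv"),
    correlation = file.path(out_dir, "correlation.csv"),
    exceedance = file.path(out_dir, "exceedance.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_csv(summaries, paths$summary, progress = FALSE)
  readr::write_csv(profiles, paths$profiles, progress = FALSE)
  readr::write_csv(accumulation, paths$accumulation, progress = FALSE)
  readr::write_csv(correlation, paths$correlation, progress = FALSE)
  readr::write_csv(exceedance, paths$exceedance, progress = FALSE)

  manifest <- list(
    records = records_input,
    limits = limits_path,
    scheme = scheme_path,
    config = normalizePath(config),
    config_md5 = unname(tools::md5sum(config)),
    seed = seed,
    alpha = alpha,
    package_version = as.character(utils::packageVersion("phytoscreen")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  done <- TRUE
  invisible(paths)
}
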