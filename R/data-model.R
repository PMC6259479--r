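# Domain types are plain tibbles with a fixed column contract; constructors
# and validators below enforce the contract so downstream stages can trust it.

ps_record_cols <- c(
  "site_id", "plot_class", "medium", "tissue", "parameter", "replicate", "value"
)

#' Build a concentration-record tibble
#'
#' One row per measured value of a (site, plot class, medium, tissue,
#' parameter, replicate) combination. Units are fixed by parameter and never
#' stored per row: pH is unitless, EC is in uS/cm, metals are in mg/kg dry
#' weight. Soil rows carry `tissue = "none"`; tissue rows name one of root,
#' leaf, fruit or stem.
#'
#' @param site_id Character site labels (e.g. `"S1"`, `"control"`). The label
#'   is free text; `plot_class` alone decides test vs control.
#' @param plot_class `"test"` or `"control"`.
#' @param medium `"soil"` or `"tissue"`.
#' @param tissue One of `"root"`, `"leaf"`, `"fruit"`, `"stem"`, or `"none"`
#'   (required for and only for soil rows).
#' @param parameter One of `"pH"`, `"EC"`, `"Pb"`, `"Hg"`, `"Cd"`, `"Cu"`,
#'   `"Zn"`.
#' @param replicate Positive integer replicate index.
#' @param value Measured value.
#' @return A tibble with the seven record columns, types coerced.
#' @export
concentration_records <- function(site_id, plot_class, medium, tissue,
                                  parameter, replicate, value) {
  rec <- tibble::tibble(
    site_id = as.character(site_id),
    plot_class = as.character(plot_class),
    medium = as.character(medium),
    tissue = as.character(tissue),
    parameter = as.character(parameter),
    replicate = as.integer(replicate),
    value = as.double(value)
  )
  check_record_vocab(rec)
  rec
}

check_record_vocab <- function(rec) {
  bad <- function(col, allowed) {
    x <- setdiff(unique(rec[[col]]), allowed)
    if (length(x) > 0) {
      abort(sprintf(
        "invalid %s value(s): %s (allowed: %s)",
        col, paste(x, collapse = ", "), paste(allowed, collapse = ", ")
      ))
    }
  }
  bad("plot_class", ps_plot_classes)
  bad("medium", ps_media)
  bad("tissue", c(ps_tissues, "none"))
  bad("parameter", ps_parameters)
  if (any(rec$replicate < 1L, na.rm = TRUE)) {
    abort("replicate must be a positive integer")
  }
  invisible(rec)
}

#' Read a long-format concentration table from CSV
#'
#' The canonical file layout is one row per measurement with header
#' `site_id, plot_class, medium, tissue, parameter, replicate, value`.
#' Files using other column names are mapped through `dialect`, a named
#' character vector of `canonical = "file column"` pairs.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#' @param dialect Optional named character vector renaming file columns onto
#'   the canonical names, e.g. `c(site_id = "station", value = "conc")`.
#' @return A concentration-record tibble (row order preserved from the file).
#' @seealso [validate_records()] for content checks beyond parsing.
#' @export
read_concentration_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(raw)) {
        abort(sprintf("dialect names column '%s' which is absent from %s", src, path))
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing <- setdiff(ps_record_cols, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  value_num <- suppressWarnings(as.double(raw$value))
  bad_rows <- which(!is.na(raw$value) & is.na(value_num))
  if (length(bad_rows) > 0) {
    # +1 for the header: report the physical line number
    abort(sprintf(
      "unparseable value '%s' at line %d of %s",
      raw$value[bad_rows[1]], bad_rows[1] + 1L, path
    ))
  }
  rep_num <- suppressWarnings(as.integer(raw$replicate))
  bad_rep <- which(!is.na(raw$replicate) & is.na(rep_num))
  if (length(bad_rep) > 0) {
    abort(sprintf("unparseable replicate at line %d of %s", bad_rep[1] + 1L, path))
  }
  concentration_records(
    raw$site_id, raw$plot_class, raw$medium, raw$tissue,
    raw$parameter, rep_num, value_num
  )
}

#' Write a concentration table to CSV
#'
#' Inverse of [read_concentration_table()]: a written file read back
#' reproduces the records field-for-field.
#'
#' @param records A concentration-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(records, path) {
  check_record_vocab(records)
  readr::write_csv(records[ps_record_cols], path, progress = FALSE)
  invisible(path)
}

#' Read a regulatory-limit table
#'
#' Expects CSV columns `authority, medium, parameter, low, high`. A single
#' limit is given with `low == high` (or `high` blank); ranged limits (such
#' as the WHO plant-tissue mercury limit 0.05-0.5 mg/kg) use both columns.
#' Ranges are normalized so `limit_low <= limit_high`.
#'
#' @param path Path to the limits CSV.
#' @return A tibble with columns `authority`, `medium`, `parameter`,
#'   `limit_low`, `limit_high`.
#' @export
read_limits <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    authority = readr::col_character(),
    medium = readr::col_character(),
    parameter = readr::col_character(),
    low = readr::col_double(),
    high = readr::col_double()
  ), progress = FALSE)
  missing <- setdiff(c("authority", "medium", "parameter", "low", "high"), names(raw))
  if (length(missing) > 0) {
    abort(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  high <- ifelse(is.na(raw$high), raw$low, raw$high)
  lim <- tibble::tibble(
    authority = raw$authority,
    medium = raw$medium,
    parameter = raw$parameter,
    limit_low = pmin(raw$low, high),
    limit_high = pmax(raw$low, high)
  )
  if (any(!lim$authority %in% ps_authorities)) {
    abort(sprintf(
      "unknown authority: %s",
      paste(setdiff(lim$authority, ps_authorities), collapse = ", ")
    ))
  }
  if (any(!lim$medium %in% ps_media)) abort("medium must be 'soil' or 'tissue'")
  if (any(lim$limit_low <= 0)) {
    bad <- lim[lim$limit_low <= 0, ]
    abort(sprintf(
      "non-positive limit for %s %s (%s)",
      bad$authority[1], bad$parameter[1], bad$medium[1]
    ))
  }
  lim
}

#' Validate concentration records (and optionally summaries)
#'
#' Screens parsed data for content problems before any computation: negative
#' concentrations, pH outside [0, 14], soil rows carrying a tissue label (or
#' tissue rows without one), duplicated record keys, and — for summary rows —
#' inverted min/max ranges. Findings are returned, never raised, so a report
#' can cover the whole file; printed-table typos (such as an inverted
#' min/max) are flagged for the analyst rather than silently repaired.
#'
#' @param records A concentration-record tibble (may be empty).
#' @param summaries Optional group-summary tibble (see [load_summary_table()])
#'   to screen for inverted ranges and negative SDs.
#' @return A validation-report tibble with columns `reference`, `rule`,
#'   `severity` (`"error"` or `"warning"`), `message`. Zero rows mean all
#'   rules passed.
#' @export
validate_records <- function(records = NULL, summaries = NULL) {
  findings <- list()
  add <- function(reference, rule, severity, message) {
    findings[[length(findings) + 1L]] <<- tibble::tibble(
      reference = reference, rule = rule, severity = severity, message = message
    )
  }

  if (!is.null(records) && nrow(records) > 0) {
    check_record_vocab(records)
    ref <- sprintf(
      "%s/%s/%s/%s/rep%d",
      records$site_id, records$medium, records$tissue, records$parameter,
      records$replicate
    )
    neg <- records$parameter != "pH" & records$value < 0
    for (i in which(neg)) {
      add(ref[i], "negative_concentration", "error",
          sprintf("negative concentration %g", records$value[i]))
    }
    bad_ph <- records$parameter == "pH" & (records$value < 0 | records$value > 14)
    for (i in which(bad_ph)) {
      add(ref[i], "ph_out_of_range", "error",
          sprintf("pH %g outside [0, 14]", records$value[i]))
    }
    soil_tissue <- records$medium == "soil" & records$tissue != "none"
    for (i in which(soil_tissue)) {
      add(ref[i], "tissue_on_soil", "error", "tissue set for soil record")
    }
    tissue_none <- records$medium == "tissue" & records$tissue == "none"
    for (i in which(tissue_none)) {
      add(ref[i], "missing_tissue", "error", "tissue record without a tissue label")
    }
    key <- paste(records$site_id, records$medium, records$tissue,
                 records$parameter, records$replicate, sep = "|")
    dup <- unique(key[duplicated(key)])
    for (k in dup) {
      add(k, "duplicate_key", "error",
          "duplicated (site, medium, tissue, parameter, replicate) key")
    }
  }

  if (!is.null(summaries) && nrow(summaries) > 0) {
    sref <- sprintf(
      "%s/%s/%s/%s",
      summaries$plot_class, summaries$medium, summaries$tissue, summaries$parameter
    )
    inv <- !is.na(summaries$min) & !is.na(summaries$max) & summaries$min > summaries$max
    for (i in which(inv)) {
      add(sref[i], "inverted_range", "warning",
          sprintf("inverted range: min %g exceeds max %g",
                  summaries$min[i], summaries$max[i]))
    }
    bad_sd <- !is.na(summaries$sd) & summaries$sd < 0
    for (i in which(bad_sd)) {
      add(sref[i], "negative_sd", "error",
          sprintf("negative standard deviation %g", summaries$sd[i]))
    }
  }

  if (length(findings) == 0) {
    tibble::tibble(
      reference = character(), rule = character(),
      severity = character(), message = character()
    )
  } else {
    dplyr::bind_rows(findings)
  }
}
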