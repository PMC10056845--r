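#' Read a subnational coverage panel from a delimited text file
#'
#' Reads a long ("tidy") table of DTP1 coverage (or no-DTP prevalence)
#' estimates by country, admin-2 unit and year, validates it, and returns a
#' tibble in the package's canonical column layout. Wide tables with one
#' column per year are reshaped on read.
#'
#' The canonical columns are `country`, `admin1`, `admin2`, `year`, the value
#' column (`dtp1_coverage` or `no_dtp`, percent on the 0--100 scale) and an
#' optional `population`. Use `col_map` to map canonical names to the file's
#' actual headers, e.g. `c(country = "ADM0_CODE", admin2 = "district")`.
#'
#' @param path Path to a CSV file.
#' @param col_map Optional named character vector mapping canonical column
#'   names (names) to the file's column names (values).
#' @param value Which value column the file carries: `"dtp1_coverage"`
#'   (default) or `"no_dtp"`.
#' @param format `"long"` (default) or `"wide"`; a wide file has one column
#'   per year (headers like `2000` or `yr2000`), reshaped via
#'   [tidyr::pivot_longer()].
#' @param validate If `TRUE` (default) run [validate_panel()] on the result.
#' @return A tibble with the canonical panel columns.
#' @seealso [validate_panel()], [to_no_dtp()], [write_panel()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(
#'   country = "AAA", admin1 = "a1", admin2 = c("u1", "u2"),
#'   year = 2000, dtp1_coverage = c(80, 60)
#' ), f, row.names = FALSE)
#' read_panel(f)
read_panel <- function(path, col_map = NULL, value = c("dtp1_coverage", "no_dtp"),
                       format = c("long", "wide"), validate = TRUE) {
  value <- match.arg(value)
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_zd(sprintf("panel file not found: %s", path), "zd_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)

  if (!is.null(col_map)) {
    missing_src <- setdiff(unname(col_map), names(raw))
    if (length(missing_src)) {
      stop_zd(
        sprintf("col_map refers to absent column(s): %s",
                paste(missing_src, collapse = ", ")),
        "zd_schema_error"
      )
    }
    raw <- dplyr::rename(raw, !!!setNames(col_map, names(col_map)))
  }

  if (format == "wide") {
    year_cols <- grep("^[A-Za-z_]*([0-9]{4})$", names(raw), value = TRUE)
    if (!length(year_cols)) {
      stop_zd("wide format requested but no year-like columns found",
              "zd_schema_error")
    }
    raw <- tidyr::pivot_longer(raw, dplyr::all_of(year_cols),
                               names_to = "year", values_to = value)
    raw$year <- as.integer(sub("^[A-Za-z_]*", "", raw$year))
  }

  required <- c("country", "admin2", "year", value)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop_zd(
      sprintf("panel is missing required column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "zd_schema_error"
    )
  }
  if (!"admin1" %in% names(raw)) raw$admin1 <- NA_character_

  keep <- c("country", "admin1", "admin2", "year", value,
            intersect("population", names(raw)))
  panel <- tibble::as_tibble(raw[keep])
  panel$year <- as.integer(panel$year)
  if (validate) validate_panel(panel, value = value)
  panel
}

#' Validate a subnational panel
#'
#' Checks the structural invariants the downstream metrics assume: required
#' columns present, values on the percent scale within \[0, 100\], no
#' duplicated (country, admin2, year) keys, non-negative populations, and a
#' constant unit set per country across years (a message, not an error, since
#' administrative splits do occur in real series).
#'
#' @param panel A panel tibble as returned by [read_panel()].
#' @param value Name of the value column to validate.
#' @return The panel, invisibly; errors of class `zd_schema_error` /
#'   `zd_validation_error` describe the offending rows.
#' @export
validate_panel <- function(panel, value = c("dtp1_coverage", "no_dtp")) {
  value <- match.arg(value)
  required <- c("country", "admin2", "year", value)
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols)) {
    stop_zd(
      sprintf("panel is missing required column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "zd_schema_error"
    )
  }
  check_percent(panel[[value]], value)
  key <- paste(panel$country, panel$admin2, panel$year, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_zd(
      sprintf("duplicate (country, admin2, year) key at row%s %s",
              if (length(dup) > 1) "s" else "",
              paste(head(dup, 5L), collapse = ", ")),
      "zd_validation_error"
    )
  }
  if ("population" %in% names(panel)) {
    bad <- which(!is.na(panel$population) & panel$population < 0)
    if (length(bad)) {
      stop_zd(
        sprintf("negative population at row%s %s",
                if (length(bad) > 1) "s" else "",
                paste(head(bad, 5L), collapse = ", ")),
        "zd_validation_error"
      )
    }
  }
  units_per_year <- dplyr::summarise(
    dplyr::group_by(panel, .data$country, .data$year),
    n = dplyr::n_distinct(.data$admin2), .groups = "drop_last"
  )
  uneven <- dplyr::filter(
    dplyr::summarise(units_per_year, k = dplyr::n_distinct(.data$n),
                     .groups = "drop"),
    .data$k > 1
  )
  if (nrow(uneven)) {
    inform(sprintf(
      "unit set varies across years for: %s",
      paste(uneven$country, collapse = ", ")
    ))
  }
  invisible(panel)
}

#' Convert between DTP1 coverage and no-DTP prevalence
#'
#' The zero-dose indicator used throughout the package is no-DTP prevalence,
#' the percentage of under-one children with no doses of a DTP-containing
#' vaccine: `no_dtp = 100 - dtp1_coverage`. Applied to a panel that already
#' carries `no_dtp`, the conversion is inverted, so the function is an
#' involution: `to_no_dtp(to_no_dtp(x))` returns `x`.
#'
#' @param panel A panel tibble carrying either `dtp1_coverage` or `no_dtp`.
#' @return The panel with the value column replaced by its complement.
#' @export
#' @examples
#' p <- tibble::tibble(country = "AAA", admin1 = NA, admin2 = "u1",
#'                     year = 2000L, dtp1_coverage = 48.1)
#' to_no_dtp(p)$no_dtp  # 51.9
to_no_dtp <- function(panel) {
  if ("no_dtp" %in% names(panel)) {
    from <- "no_dtp"; to <- "dtp1_coverage"
  } else if ("dtp1_coverage" %in% names(panel)) {
    from <- "dtp1_coverage"; to <- "no_dtp"
  } else {
    stop_zd("panel carries neither 'dtp1_coverage' nor 'no_dtp'",
            "zd_schema_error")
  }
  check_percent(panel[[from]], from)
  out <- panel
  out[[to]] <- 100 - out[[from]]
  out[[from]] <- NULL
  # keep the value column in its canonical position (after year)
  lead <- intersect(c("country", "admin1", "admin2", "year"), names(out))
  dplyr::relocate(out, dplyr::all_of(to), .after = dplyr::all_of(lead[length(lead)]))
}

#' Write a panel (or any metrics table) to CSV at fixed precision
#'
#' @param x A tibble.
#' @param path Output path.
#' @param digits Decimal places for numeric (double) columns; default 1,
#'   matching the precision of published coverage estimates.
#' @return `path`, invisibly.
#' @export
write_panel <- function(x, path, digits = 1) {
  out <- dplyr::mutate(x, dplyr::across(
    dplyr::where(function(col) is.double(col) && !is.integer(col)),
    function(col) round(col, digits)
  ))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

zd_extdata <- function(file) {
  path <- system.file("extdata", file, package = "zerodose")
  if (!nzchar(path)) {
    stop_zd(sprintf("bundled resource not found: %s", file), "zd_io_error")
  }
  path
}

#' Load the bundled published-results fixture
#'
#' Returns the transcription of the published country-level results the
#' package validates against: 2000 and 2019 national no-DTP prevalence and
#' 5th--95th percentile subnational gaps for the 56 study countries, the
#' printed absolute/relative change columns, exemplar flags, and the printed
#' 5th/95th percentile endpoints for the five exemplar countries. (The 2019
#' percentile endpoints for Bangladesh were never printed -- only its ~0.01 pp
#' gap -- so that row is absent from `$percentiles`.)
#'
#' Note the printed change columns were derived from unrounded source
#' estimates, so they can differ from changes recomputed from the rounded
#' printed levels by up to ~0.1 pp (e.g. India's national change prints -23.6
#' while 7.2 - 30.9 = -23.7).
#'
#' @return A list of class `zd_table2` with elements `countries` (56-row
#'   tibble) and `percentiles` (exemplar endpoint tibble).
#' @export
load_table2_fixture <- function() {
  countries <- readr::read_csv(zd_extdata("table2_levels.csv"),
                               show_col_types = FALSE, progress = FALSE)
  percentiles <- readr::read_csv(zd_extdata("exemplar_percentiles.csv"),
                                 show_col_types = FALSE, progress = FALSE)
  if (nrow(countries) != 56L) {
    stop_zd("corrupted fixture: expected 56 countries", "zd_io_error")
  }
  structure(list(countries = countries, percentiles = percentiles),
            class = "zd_table2")
}

#' Load bundled country metadata
#'
#' Income group, Gavi support, zero-dose segmentation group and Learning Hub
#' flag for the 56 study countries. The Learning Hub countries (targets of
#' the neighborhood analysis) are Nigeria, Mali, Uganda and Bangladesh.
#'
#' @return A 56-row tibble.
#' @export
load_country_meta <- function() {
  meta <- readr::read_csv(zd_extdata("country_meta.csv"),
                          show_col_types = FALSE, progress = FALSE)
  stopifnot(!anyDuplicated(meta$country))
  meta
}

#' Endpoint-year metrics table from the published fixture
#'
#' Reshapes the fixture into the country-year metrics layout used by
#' [change_metrics()] and the neighborhood functions: one row per country and
#' endpoint year (2000, 2019) with `national_no_dtp`, `p5`, `p95` (known only
#' for the exemplar countries) and `gap`.
#'
#' @param fixture A `zd_table2` object from [load_table2_fixture()].
#' @return A 112-row tibble (56 countries x 2 years).
#' @export
table2_metrics <- function(fixture = load_table2_fixture()) {
  long <- tidyr::pivot_longer(
    fixture$countries,
    cols = c("national_2000", "national_2019", "gap_2000", "gap_2019"),
    names_to = c("metric", "year"), names_sep = "_(?=[0-9]{4}$)",
    values_to = "value"
  )
  long$year <- as.integer(long$year)
  wide <- tidyr::pivot_wider(
    long[, c("country", "iso3", "year", "metric", "value")],
    names_from = "metric", values_from = "value"
  )
  wide <- dplyr::rename(wide, national_no_dtp = "national")
  out <- dplyr::left_join(
    wide, fixture$percentiles[, c("country", "year", "p5", "p95")],
    by = c("country", "year")
  )
  dplyr::arrange(out[, c("country", "iso3", "year", "national_no_dtp",
                         "p5", "p95", "gap")],
                 .data$country, .data$year)
}
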