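#' Subnational percentile gap
#'
#' The package's inequality statistic: the difference between the 95th and
#' 5th percentiles of no-DTP prevalence across a country's admin-2 units in a
#' year. Percentiles (rather than min/max) damp the influence of single
#' outlying units and of widely varying unit counts (from fewer than 10 units
#' in the smallest countries to 774 LGAs in Nigeria).
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7), pinned for reproducibility. With a single
#' unit the gap is 0 by construction. Optional `weights` switch to a
#' population-weighted quantile (linear interpolation on the cumulative
#' weight midpoints).
#'
#' @param values Numeric vector of unit no-DTP prevalences (percent, 0--100).
#' @param lower,upper Quantile probabilities; defaults 0.05 and 0.95.
#' @param weights Optional non-negative weights (e.g. unit populations).
#' @return A one-row tibble with `p5`, `p95` and `gap = p95 - p5`.
#' @export
#' @examples
#' subnational_gap(c(28.5, 40, 60, 75.3))
subnational_gap <- function(values, lower = 0.05, upper = 0.95, weights = NULL) {
  if (!length(values) || all(is.na(values))) {
    stop_zd("subnational_gap needs at least one non-missing value",
            "zd_validation_error")
  }
  if (!(lower >= 0 && lower < upper && upper <= 1)) {
    stop_zd("quantile bounds must satisfy 0 <= lower < upper <= 1",
            "zd_validation_error")
  }
  values <- values[!is.na(values)]
  if (is.null(weights)) {
    q <- unname(quantile(values, probs = c(lower, upper), type = 7))
  } else {
    if (length(weights) < length(values)) {
      stop_zd("weights must match values in length", "zd_validation_error")
    }
    q <- c(weighted_quantile(values, weights, lower),
           weighted_quantile(values, weights, upper))
  }
  tibble::tibble(p5 = q[1], p95 = q[2], gap = q[2] - q[1])
}

# Weighted quantile: linear interpolation at cumulative-weight midpoints,
# reducing to something close to type 7 for equal weights.
weighted_quantile <- function(x, w, p) {
  keep <- !is.na(x)
  x <- x[keep]; w <- w[keep]
  if (any(w < 0)) stop_zd("weights must be non-negative", "zd_validation_error")
  if (sum(w) <= 0) stop_zd("weights sum to zero", "zd_validation_error")
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  mid <- (cw - w / 2) / sum(w)
  if (p <= mid[1]) return(x[1])
  if (p >= mid[length(mid)]) return(x[length(x)])
  stats::approx(mid, x, xout = p, ties = "ordered")$y
}

#' National no-DTP series
#'
#' One national value per country-year, from one of three sources: a
#' `provided` table of national estimates (the study design, where national
#' series are modelled independently of the subnational units), a
#' population-weighted mean of unit values, or an unweighted unit mean.
#'
#' @param panel No-DTP panel tibble (`country`, `admin2`, `year`, `no_dtp`,
#'   optional `population`).
#' @param mode `"unweighted_mean"` (default), `"pop_weighted"` or
#'   `"provided"`.
#' @param national_table For `mode = "provided"`: tibble with `country`,
#'   `year`, `national_no_dtp`.
#' @return Tibble with `country`, `year`, `national_no_dtp`.
#' @export
national_series <- function(panel,
                            mode = c("unweighted_mean", "pop_weighted", "provided"),
                            national_table = NULL) {
  mode <- match.arg(mode)
  if (mode == "provided") {
    if (is.null(national_table)) {
      stop_zd("mode = 'provided' requires a national_table", "zd_schema_error")
    }
    need <- unique(panel[, c("country", "year")])
    out <- dplyr::left_join(need, national_table, by = c("country", "year"))
    miss <- out[is.na(out$national_no_dtp), , drop = FALSE]
    if (nrow(miss)) {
      stop_zd(
        sprintf("national_table lacks rows for: %s",
                paste(head(paste0(miss$country, ":", miss$year), 5L),
                      collapse = ", ")),
        "zd_validation_error"
      )
    }
    return(dplyr::arrange(out, .data$country, .data$year))
  }
  if (mode == "pop_weighted") {
    if (!"population" %in% names(panel) || all(is.na(panel$population))) {
      stop_zd("mode = 'pop_weighted' requires a population column",
              "zd_schema_error")
    }
    out <- dplyr::summarise(
      dplyr::group_by(panel, .data$country, .data$year),
      national_no_dtp = {
        if (sum(.data$population, na.rm = TRUE) <= 0) {
          stop_zd("zero total population in a country-year",
                  "zd_validation_error")
        }
        sum(.data$population * .data$no_dtp, na.rm = TRUE) /
          sum(.data$population, na.rm = TRUE)
      },
      .groups = "drop"
    )
    return(dplyr::arrange(out, .data$country, .data$year))
  }
  out <- dplyr::summarise(
    dplyr::group_by(panel, .data$country, .data$year),
    national_no_dtp = mean(.data$no_dtp, na.rm = TRUE),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$country, .data$year)
}

#' Country-year metrics: national level and subnational percentile gap
#'
#' The central metrics table: for every country-year, the national no-DTP
#' prevalence plus the 5th/95th percentiles and their gap across admin-2
#' units. Percentiles are computed over units unweighted by default,
#' mirroring the unit-level treatment of the published analysis;
#' `weighted = TRUE` uses unit populations instead.
#'
#' @param panel No-DTP panel tibble.
#' @param national_mode,national_table Passed to [national_series()].
#' @param lower,upper Quantile probabilities for the gap.
#' @param weighted Use population-weighted percentiles (requires
#'   `population`).
#' @return Tibble with `country`, `year`, `national_no_dtp`, `p5`, `p95`,
#'   `gap`, `n_units`.
#' @export
country_year_metrics <- function(panel,
                                 national_mode = "unweighted_mean",
                                 national_table = NULL,
                                 lower = 0.05, upper = 0.95,
                                 weighted = FALSE) {
  if (weighted && !"population" %in% names(panel)) {
    inform("no population column: falling back to unweighted percentiles")
    weighted <- FALSE
  }
  gaps <- dplyr::reframe(
    dplyr::group_by(panel, .data$country, .data$year),
    subnational_gap(.data$no_dtp, lower, upper,
                    weights = if (weighted) .data$population else NULL),
    n_units = dplyr::n()
  )
  singletons <- unique(gaps$country[gaps$n_units == 1L])
  if (length(singletons)) {
    inform(sprintf("single-unit countr%s (gap = 0): %s",
                   if (length(singletons) > 1) "ies" else "y",
                   paste(singletons, collapse = ", ")))
  }
  nat <- national_series(panel, national_mode, national_table)
  out <- dplyr::left_join(nat, gaps, by = c("country", "year"))
  dplyr::arrange(out, .data$country, .data$year)
}

#' Absolute and relative change between two years
#'
#' For each country and each of the two geographic dimensions (national
#' level, subnational gap), computes the percentage-point change
#' (`end - start`; reductions are negative) and the percentage change
#' (`(end - start) / start * 100`). The relative change is undefined
#' (`NA`) when the start value is 0.
#'
#' @param metrics Country-year metrics tibble (needs `country`, `year`,
#'   `national_no_dtp`, `gap`).
#' @param year_start,year_end Endpoint years; defaults 2000 and 2019.
#' @return Tibble with `country`, `dimension`
#'   (`"national"`/`"subnational_gap"`), `value_start`, `value_end`,
#'   `absolute_change`, `relative_change`. Countries missing an endpoint
#'   year are dropped with a warning.
#' @export
change_metrics <- function(metrics, year_start = 2000, year_end = 2019) {
  long <- tidyr::pivot_longer(
    metrics[, c("country", "year", "national_no_dtp", "gap")],
    cols = c("national_no_dtp", "gap"),
    names_to = "dimension", values_to = "value"
  )
  long$dimension <- ifelse(long$dimension == "national_no_dtp",
                           "national", "subnational_gap")
  ends <- dplyr::filter(long, .data$year %in% c(year_start, year_end))
  wide <- tidyr::pivot_wider(
    ends, id_cols = c("country", "dimension"),
    names_from = "year", values_from = "value",
    names_prefix = "y"
  )
  sc <- paste0("y", year_start); ec <- paste0("y", year_end)
  if (!all(c(sc, ec) %in% names(wide))) {
    stop_zd(sprintf("years %d and %d not both present in metrics",
                    year_start, year_end), "zd_validation_error")
  }
  incomplete <- unique(wide$country[is.na(wide[[sc]]) | is.na(wide[[ec]])])
  if (length(incomplete)) {
    warn(sprintf("dropping countr%s missing an endpoint year: %s",
                 if (length(incomplete) > 1) "ies" else "y",
                 paste(incomplete, collapse = ", ")))
    wide <- wide[!wide$country %in% incomplete, , drop = FALSE]
  }
  out <- tibble::tibble(
    country = wide$country,
    dimension = wide$dimension,
    value_start = wide[[sc]],
    value_end = wide[[ec]],
    absolute_change = wide[[ec]] - wide[[sc]],
    relative_change = ifelse(wide[[sc]] > 0,
                             (wide[[ec]] - wide[[sc]]) / wide[[sc]] * 100,
                             NA_real_)
  )
  dplyr::arrange(out, .data$country, .data$dimension)
}

#' Four-way progress classification
#'
#' Partitions countries by the sign of their absolute change in each
#' dimension: reduction in both, national-only reduction, gap-only
#' reduction, or increase (no reduction) in both. "Reduction" means a strict
#' decrease; zero change counts as not reduced.
#'
#' @param changes Output of [change_metrics()].
#' @return Tibble with `country`, `national_change`, `gap_change`,
#'   `category` (factor with levels `both_reduced`, `national_only_reduced`,
#'   `gap_only_reduced`, `both_increased`). Countries lacking either
#'   dimension are excluded with a warning.
#' @export
classify_progress <- function(changes) {
  wide <- tidyr::pivot_wider(
    changes[, c("country", "dimension", "absolute_change")],
    names_from = "dimension", values_from = "absolute_change"
  )
  ok <- !is.na(wide$national) & !is.na(wide$subnational_gap)
  if (any(!ok)) {
    warn(sprintf("excluding countries missing a dimension: %s",
                 paste(wide$country[!ok], collapse = ", ")))
    wide <- wide[ok, , drop = FALSE]
  }
  nat_red <- wide$national < 0
  gap_red <- wide$subnational_gap < 0
  category <- dplyr::case_when(
    nat_red & gap_red ~ "both_reduced",
    nat_red & !gap_red ~ "national_only_reduced",
    !nat_red & gap_red ~ "gap_only_reduced",
    TRUE ~ "both_increased"
  )
  tibble::tibble(
    country = wide$country,
    national_change = wide$national,
    gap_change = wide$subnational_gap,
    category = factor(category, levels = c("both_reduced",
                                           "national_only_reduced",
                                           "gap_only_reduced",
                                           "both_increased"))
  )
}

#' Category counts for the progress classification
#'
#' @param quadrants Output of [classify_progress()].
#' @return Tibble of `category`, `n` and `share` (percent of countries),
#'   covering all four categories (zero counts included).
#' @export
progress_counts <- function(quadrants) {
  counts <- dplyr::count(quadrants, .data$category, .drop = FALSE)
  counts$share <- counts$n / sum(counts$n) * 100
  counts
}

#' Correlation between admin-2 unit counts and subnational gaps
#'
#' A diagnostic for whether countries carved into more admin-2 units
#' mechanically show wider percentile gaps: the Pearson correlation, across
#' countries, between the number of units and the gap in a given year.
#'
#' @param panel No-DTP panel tibble.
#' @param year Year to evaluate.
#' @param lower,upper Quantile probabilities for the gap.
#' @return Pearson r (scalar), with attributes `n` (countries used) and
#'   `year`; `NA` with a warning if either variable has zero variance.
#' @export
units_gap_correlation <- function(panel, year, lower = 0.05, upper = 0.95) {
  yr <- panel[panel$year == year, , drop = FALSE]
  if (!nrow(yr)) {
    stop_zd(sprintf("no panel rows for year %s", year), "zd_validation_error")
  }
  per_country <- dplyr::reframe(
    dplyr::group_by(yr, .data$country),
    n_units = dplyr::n(),
    gap = subnational_gap(.data$no_dtp, lower, upper)$gap
  )
  if (nrow(per_country) < 3L) {
    stop_zd("need at least 3 countries for a correlation",
            "zd_validation_error")
  }
  r <- if (sd(per_country$n_units) == 0 || sd(per_country$gap) == 0) {
    warn("zero variance in unit counts or gaps: correlation undefined")
    NA_real_
  } else {
    cor(per_country$n_units, per_country$gap)
  }
  structure(r, n = nrow(per_country), year = year)
}
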