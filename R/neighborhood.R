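#' Baseline distance between two entities
#'
#' Distance between two entities' no-DTP measures in the baseline year, used
#' to find "neighbors" -- entities that started from similar positions. On a
#' single dimension the distance is the absolute difference in percentage
#' points; on the joint (national, gap) plane it is Euclidean, optionally
#' with each axis standardized by a supplied scale (typically the candidate
#' pool's standard deviations, making the match invariant to rescaling
#' either axis).
#'
#' @param a,b Lists or one-row data frames with `national_no_dtp` and `gap`.
#' @param dimension `"joint"` (default), `"national"` or `"gap"`.
#' @param scale For `dimension = "joint"`: optional numeric
#'   `c(national, gap)` scale divisors.
#' @return Non-negative scalar distance.
#' @export
#' @examples
#' baseline_distance(list(national_no_dtp = 36.4, gap = 47.8),
#'                   list(national_no_dtp = 51.9, gap = 46.8), "gap")  # 1.0
baseline_distance <- function(a, b, dimension = c("joint", "national", "gap"),
                              scale = NULL) {
  dimension <- match.arg(dimension)
  an <- a$national_no_dtp; ag <- a$gap
  bn <- b$national_no_dtp; bg <- b$gap
  need <- switch(dimension, national = c(an, bn), gap = c(ag, bg),
                 joint = c(an, ag, bn, bg))
  if (any(is.na(need)) || any(vapply(list(need), length, 1L) == 0)) {
    stop_zd("baseline metrics missing for one of the entities",
            "zd_validation_error")
  }
  switch(dimension,
    national = abs(an - bn),
    gap = abs(ag - bg),
    joint = {
      s <- scale %||% c(1, 1)
      if (any(s <= 0)) stop_zd("scale must be positive", "zd_validation_error")
      sqrt(((an - bn) / s[1])^2 + ((ag - bg) / s[2])^2)
    }
  )
}

entity_row <- function(metrics, entity, year, id) {
  row <- metrics[metrics[[id]] == entity & metrics$year == year, , drop = FALSE]
  if (!nrow(row)) {
    stop_zd(sprintf("no metrics for %s in %s", entity, year),
            "zd_validation_error")
  }
  row[1, , drop = FALSE]
}

#' Match a target entity to its nearest baseline neighbor
#'
#' Finds, within a candidate pool, the entity whose baseline-year no-DTP
#' measures lie closest to the target's, and reports the end-year divergence
#' (matched minus target) on both dimensions. For joint matching with
#' `standardize = TRUE` (the default) each axis is divided by the pool's
#' standard deviation at baseline, so neither metric dominates by units
#' alone. Distance ties are broken alphabetically.
#'
#' @param target Entity identifier.
#' @param pool Character vector of candidate entities (the target itself is
#'   dropped if present).
#' @param metrics Metrics tibble with the `id` column, `year`,
#'   `national_no_dtp` and `gap` (e.g. [country_year_metrics()] or
#'   [table2_metrics()] output).
#' @param baseline_year,end_year Matching year and divergence year.
#' @param dimension `"joint"`, `"national"` or `"gap"`.
#' @param standardize Standardize the joint plane by pool SDs.
#' @param id Name of the entity column; `"country"` by default (use
#'   `"admin1"` with [admin1_metrics()] for within-country analyses).
#' @return One-row tibble: `target`, `matched`, `dimension`,
#'   `baseline_year`, `distance`, `divergence_national`, `divergence_gap`.
#' @export
match_neighbor <- function(target, pool, metrics,
                           baseline_year = 2000, end_year = 2019,
                           dimension = c("joint", "national", "gap"),
                           standardize = TRUE, id = "country") {
  dimension <- match.arg(dimension)
  pool <- sort(setdiff(unique(pool), target))
  if (!length(pool)) stop_zd("empty candidate pool", "zd_validation_error")
  tgt <- entity_row(metrics, target, baseline_year, id)
  cand <- lapply(pool, entity_row, metrics = metrics, year = baseline_year,
                 id = id)
  scale <- NULL
  if (dimension == "joint" && standardize) {
    nats <- vapply(cand, function(r) r$national_no_dtp, numeric(1))
    gaps <- vapply(cand, function(r) r$gap, numeric(1))
    scale <- c(if (length(cand) > 1 && sd(nats) > 0) sd(nats) else 1,
               if (length(cand) > 1 && sd(gaps) > 0) sd(gaps) else 1)
  }
  dists <- vapply(cand, baseline_distance, numeric(1), a = tgt,
                  dimension = dimension, scale = scale)
  best <- pool[which.min(dists)]  # pool is sorted, so ties go alphabetically
  tgt_end <- entity_row(metrics, target, end_year, id)
  mat_end <- entity_row(metrics, best, end_year, id)
  tibble::tibble(
    target = target,
    matched = best,
    dimension = dimension,
    baseline_year = baseline_year,
    distance = min(dists),
    divergence_national = mat_end$national_no_dtp - tgt_end$national_no_dtp,
    divergence_gap = mat_end$gap - tgt_end$gap
  )
}

#' Match target countries to exemplars, each exemplar used at most once
#'
#' Sequentially matches each target (by default the Gavi Learning Hub
#' countries in their published order) to its nearest remaining exemplar,
#' removing each matched exemplar from the pool before the next target is
#' considered. Without-replacement matching yields a set of distinct
#' target--exemplar pairings suited to one-to-one cross-country learning; set
#' `without_replacement = FALSE` to match every target against the full
#' pool independently.
#'
#' @param metrics Metrics tibble (see [match_neighbor()]).
#' @param targets Character vector of target entities, in matching order.
#' @param pool Candidate exemplars.
#' @param dimensions Matching dimension per target (recycled), e.g.
#'   `c("joint", "gap", "national")`.
#' @param baseline_year,end_year,standardize,id As in [match_neighbor()].
#' @param without_replacement Drop each matched exemplar from later pools.
#' @return Tibble with one [match_neighbor()] row per target.
#' @export
match_learning_hubs <- function(metrics, targets, pool,
                                dimensions = "joint",
                                baseline_year = 2000, end_year = 2019,
                                standardize = TRUE, id = "country",
                                without_replacement = TRUE) {
  dimensions <- rep_len(dimensions, length(targets))
  remaining <- setdiff(pool, targets)
  out <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    if (!length(remaining)) {
      stop_zd("candidate pool exhausted before all targets were matched",
              "zd_validation_error")
    }
    m <- match_neighbor(targets[i], remaining, metrics,
                        baseline_year = baseline_year, end_year = end_year,
                        dimension = dimensions[i], standardize = standardize,
                        id = id)
    out[[i]] <- m
    if (without_replacement) remaining <- setdiff(remaining, m$matched)
  }
  dplyr::bind_rows(out)
}

#' Paired trajectory table for a target and its matched neighbor
#'
#' Year-by-year national levels and subnational gaps for both entities, plus
#' per-year differences (matched minus target). The published comparisons
#' are descriptive: divergence is reported as the difference vector, with no
#' statistical test attached.
#'
#' @param target,matched Entity identifiers.
#' @param metrics Metrics tibble.
#' @param years Optional year vector; defaults to the years both entities
#'   share.
#' @param id Entity column name.
#' @return Tibble with `year`, `target_national`, `match_national`,
#'   `target_gap`, `match_gap`, `diff_national`, `diff_gap`.
#' @export
divergence_report <- function(target, matched, metrics, years = NULL,
                              id = "country") {
  tgt <- metrics[metrics[[id]] == target, , drop = FALSE]
  mat <- metrics[metrics[[id]] == matched, , drop = FALSE]
  shared <- intersect(tgt$year, mat$year)
  if (!is.null(years)) shared <- intersect(shared, years)
  shared <- sort(shared)
  if (!length(shared)) {
    stop_zd("no overlapping year coverage for the pair", "zd_validation_error")
  }
  tgt <- tgt[match(shared, tgt$year), , drop = FALSE]
  mat <- mat[match(shared, mat$year), , drop = FALSE]
  tibble::tibble(
    year = shared,
    target_national = tgt$national_no_dtp,
    match_national = mat$national_no_dtp,
    target_gap = tgt$gap,
    match_gap = mat$gap,
    diff_national = mat$national_no_dtp - tgt$national_no_dtp,
    diff_gap = mat$gap - tgt$gap
  )
}

#' Admin-1 metrics for within-country neighborhood analysis
#'
#' Aggregates a no-DTP panel to first-administrative-level entities within
#' one country: the admin-1 "national" level is the (optionally
#' population-weighted) mean over its admin-2 units, and the gap is the
#' 5th--95th percentile difference across those units. The result plugs
#' directly into [match_neighbor()] and [divergence_report()] with
#' `id = "admin1"`, so the same machinery compares, say, bordering states
#' instead of countries.
#'
#' @param panel No-DTP panel tibble.
#' @param country Country to subset to.
#' @param lower,upper Quantile probabilities for the gap.
#' @param weighted Population-weight the admin-1 mean.
#' @return Tibble with `admin1`, `year`, `national_no_dtp`, `p5`, `p95`,
#'   `gap`, `n_units`.
#' @export
admin1_metrics <- function(panel, country, lower = 0.05, upper = 0.95,
                           weighted = FALSE) {
  sub <- panel[panel$country == country, , drop = FALSE]
  if (!nrow(sub)) {
    stop_zd(sprintf("no panel rows for country %s", country),
            "zd_validation_error")
  }
  if (any(is.na(sub$admin1))) {
    stop_zd("admin1 identifiers required for within-country analysis",
            "zd_validation_error")
  }
  dplyr::reframe(
    dplyr::group_by(sub, .data$admin1, .data$year),
    national_no_dtp = if (weighted && "population" %in% names(sub)) {
      sum(.data$population * .data$no_dtp) / sum(.data$population)
    } else {
      mean(.data$no_dtp)
    },
    subnational_gap(.data$no_dtp, lower, upper),
    n_units = dplyr::n()
  )
}
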