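#' Per-country change scatter (plot-ready coordinates)
#'
#' One row per country with the absolute change in each dimension, the
#' progress-quadrant category, and (when metrics are supplied) the end-year
#' national level used for colour-coding.
#'
#' @param changes Output of [change_metrics()].
#' @param metrics Optional country-year metrics for the end-year level.
#' @param year_end End year for the level column.
#' @return Tibble with `country`, `national_change`, `gap_change`,
#'   `category`, `national_end`.
#' @export
export_change_scatter <- function(changes, metrics = NULL, year_end = 2019) {
  quad <- classify_progress(changes)
  out <- quad
  out$national_end <- NA_real_
  if (!is.null(metrics)) {
    ends <- metrics[metrics$year == year_end,
                    c("country", "national_no_dtp")]
    out$national_end <- ends$national_no_dtp[match(out$country, ends$country)]
  }
  out
}

#' Phase-plane trajectories (national level vs subnational gap)
#'
#' Ordered per-year (national, gap) coordinates per entity, the layout
#' behind phase plots where progress moves trajectories toward the
#' low-level / low-gap corner. Entities can be highlighted (e.g.
#' `"exemplar"`, `"learning_hub"`); names absent from the metrics are
#' dropped with a warning.
#'
#' @param metrics Country-year metrics tibble.
#' @param highlight Optional named character vector mapping entity to
#'   highlight label.
#' @param id Entity column name.
#' @return Tibble with `id` column, `year`, `national_no_dtp`, `gap`,
#'   `highlight` (`"other"` where unhighlighted), ordered by entity and
#'   year.
#' @export
export_phase_trajectories <- function(metrics, highlight = NULL,
                                      id = "country") {
  out <- metrics[, c(id, "year", "national_no_dtp", "gap")]
  out <- dplyr::arrange(out, .data[[id]], .data$year)
  out$highlight <- "other"
  if (!is.null(highlight)) {
    unknown <- setdiff(names(highlight), out[[id]])
    if (length(unknown)) {
      warn(sprintf("unknown highlight entit%s ignored: %s",
                   if (length(unknown) > 1) "ies" else "y",
                   paste(unknown, collapse = ", ")))
    }
    hit <- match(out[[id]], names(highlight))
    out$highlight <- ifelse(is.na(hit), "other", unname(highlight)[hit])
  }
  tibble::as_tibble(out)
}

default_config <- function() {
  list(
    input = list(mode = "fixture"),
    analysis = list(year_start = 2000, year_end = 2019,
                    lower = 0.05, upper = 0.95,
                    national_mode = "unweighted_mean",
                    top_k_absolute = 3, top_k_relative = 2),
    neighborhood = list(baseline_year = 2000, end_year = 2019,
                        dimensions = "joint", without_replacement = TRUE),
    output = list(digits = 1)
  )
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Run the full exemplar-identification pipeline
#'
#' Orchestrates every stage -- ingestion, country-year metrics, change
#' metrics, progress classification, dual-track ranking and exemplar
#' selection, neighborhood matching, and plot-coordinate export -- and
#' writes each stage's table plus a run manifest (config hash, seed, file
#' digests) to `out`. Re-running with an identical config and seed
#' reproduces byte-identical tables.
#'
#' The config is a nested list (or path to a YAML file) with blocks:
#' \describe{
#'   \item{input}{`mode`: `"fixture"` (bundled published endpoint tables),
#'     `"panel"` (`panel` CSV path, optional `national` table path, `value`,
#'     `col_map`), or `"synthetic"` (`synthetic`: [synthetic_spec()]
#'     overrides).}
#'   \item{analysis}{`year_start`, `year_end`, `lower`, `upper`,
#'     `national_mode`, `top_k_absolute`, `top_k_relative`.}
#'   \item{neighborhood}{`targets` (omit to skip the stage in non-fixture
#'     modes; fixture mode defaults to the Learning Hub countries other
#'     than Bangladesh), `dimensions`, `baseline_year`, `end_year`,
#'     `without_replacement`.}
#'   \item{output}{`digits` for written tables (default 1).}
#' }
#'
#' @param config Nested list or YAML file path; `list()` uses fixture-mode
#'   defaults.
#' @param out Output directory (created if needed); `NULL` computes without
#'   writing.
#' @param seed Overrides the synthetic-mode seed.
#' @return Invisibly, a list with every stage table and the manifest.
#' @export
run_pipeline <- function(config = list(), out = NULL, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop_zd(sprintf("config file not found: %s", config), "zd_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stop_zd("config must be a list or a YAML file path", "zd_usage_error")
  }
  cfg <- merge_config(default_config(), config)
  if (!is.null(seed)) cfg$input$synthetic$seed <- seed
  mode <- cfg$input$mode %||% "fixture"
  an <- cfg$analysis

  truth <- NULL
  if (mode == "fixture") {
    metrics <- table2_metrics()
    inform("stage metrics: fixture endpoint mode, 56 countries")
  } else if (mode == "panel") {
    if (is.null(cfg$input$panel)) {
      stop_zd("input$panel path required in panel mode", "zd_usage_error")
    }
    panel <- read_panel(cfg$input$panel,
                        col_map = unlist(cfg$input$col_map) %||% NULL,
                        value = cfg$input$value %||% "dtp1_coverage")
    if (!"no_dtp" %in% names(panel)) panel <- to_no_dtp(panel)
    national_table <- if (!is.null(cfg$input$national)) {
      readr::read_csv(cfg$input$national, show_col_types = FALSE,
                      progress = FALSE)
    }
    metrics <- country_year_metrics(
      panel, national_mode = an$national_mode,
      national_table = national_table, lower = an$lower, upper = an$upper
    )
    inform(sprintf("stage metrics: %d countries from panel",
                   dplyr::n_distinct(metrics$country)))
  } else if (mode == "synthetic") {
    spec <- do.call(synthetic_spec, cfg$input$synthetic %||% list())
    study <- generate_study(spec)
    truth <- study$truth
    panel <- to_no_dtp(study$panel)
    metrics <- country_year_metrics(panel, national_mode = an$national_mode,
                                    lower = an$lower, upper = an$upper)
    inform(sprintf("stage metrics: %d synthetic countries, seed %d",
                   spec$n_countries, spec$seed))
  } else {
    stop_zd(sprintf("unknown input mode: %s", mode), "zd_usage_error")
  }

  changes <- change_metrics(metrics, an$year_start, an$year_end)
  quadrants <- classify_progress(changes)
  counts <- progress_counts(quadrants)
  inform(sprintf("stage classify: %d countries, %d with reductions in both",
                 nrow(quadrants), counts$n[counts$category == "both_reduced"]))

  rank_abs <- select_exemplars(ranking_table(changes, "absolute"),
                               k = an$top_k_absolute)
  rank_rel <- select_exemplars(ranking_table(changes, "relative"),
                               k = an$top_k_relative)
  exemplars <- dplyr::bind_rows(
    rank_abs[rank_abs$exemplar, c("country", "track", "mean_rank")],
    rank_rel[rank_rel$exemplar, c("country", "track", "mean_rank")]
  )
  inform(sprintf("stage rank: exemplars = %s",
                 paste(unique(exemplars$country), collapse = ", ")))

  nb <- cfg$neighborhood
  targets <- nb$targets
  if (is.null(targets) && mode == "fixture") {
    hubs <- load_country_meta()
    targets <- setdiff(hubs$country[hubs$learning_hub],
                       unique(exemplars$country))
  }
  matches <- NULL
  if (!is.null(targets) && length(targets)) {
    pool <- nb$pool %||% unique(exemplars$country)
    matches <- match_learning_hubs(
      metrics, targets = targets, pool = pool,
      dimensions = unlist(nb$dimensions) %||% "joint",
      baseline_year = nb$baseline_year %||% an$year_start,
      end_year = nb$end_year %||% an$year_end,
      without_replacement = isTRUE(nb$without_replacement)
    )
    inform(sprintf("stage neighbors: %d targets matched", nrow(matches)))
  }

  highlight <- c(
    setNames(rep("exemplar", length(unique(exemplars$country))),
             unique(exemplars$country)),
    if (!is.null(targets)) setNames(rep("learning_hub", length(targets)),
                                    targets)
  )
  trajectories <- export_phase_trajectories(metrics, highlight = highlight)
  scatter <- export_change_scatter(changes, metrics, an$year_end)

  results <- list(metrics = metrics, changes = changes,
                  quadrants = quadrants, counts = counts,
                  ranking_absolute = rank_abs, ranking_relative = rank_rel,
                  exemplars = exemplars, matches = matches,
                  trajectories = trajectories, change_scatter = scatter,
                  truth = truth)

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    digits <- cfg$output$digits %||% 1
    written <- character()
    for (nm in names(results)) {
      if (is.null(results[[nm]])) next
      path <- file.path(out, paste0(nm, ".csv"))
      write_panel(results[[nm]], path, digits = digits)
      written <- c(written, path)
    }
    manifest <- list(
      package = "zerodose",
      version = as.character(utils::packageVersion("zerodose")),
      config_hash = rlang::hash(cfg),
      seed = cfg$input$synthetic$seed %||% NA,
      files = lapply(setNames(basename(written), basename(written)),
                     function(f) {
                       unname(tools::md5sum(file.path(out, f)))
                     })
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    results$manifest <- manifest
  }
  invisible(results)
}
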