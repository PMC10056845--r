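#' Specification for a synthetic multi-country no-DTP panel
#'
#' Defines the generative model used to emulate modelled subnational
#' coverage panels. Unit trajectories live on the log-odds scale, which
#' respects the \[0, 100\] percent bounds without clipping driving the
#' dynamics: unit u of country c in year t has noiseless prevalence
#' `plogis(b_cu - r_cu * t) * 100`, where `b_cu` is the unit's baseline
#' log-odds (country mean + unit offset) and `r_cu` its annual decline rate
#' (country rate + unit offset). Bounded Gaussian observation noise is added
#' on the percent scale; optional shock blocks (emulating e.g. conflict
#' periods) add a fixed increment to a random fraction of units for an
#' interval of years.
#'
#' Defaults mirror the study conditions: 56 countries observed 2000--2019
#' with admin-2 unit counts spanning roughly 8 to 800, country baselines
#' spread so 2000 national no-DTP ranges from a few percent to above 50%,
#' and heterogeneous decline rates including occasional worsening countries.
#'
#' @param n_countries Number of countries (default 56).
#' @param years Calendar years covered (default 2000:2019).
#' @param n_units_range Range of admin-2 unit counts; counts are drawn
#'   log-uniformly so small-unit countries are common, as in real
#'   administrative geographies.
#' @param baseline_logit_mean,baseline_logit_sd Country-level baseline
#'   no-DTP distribution on the log-odds scale (default centre
#'   `qlogis(0.2)`, i.e. 20% no-DTP).
#' @param unit_logit_sd Within-country unit baseline dispersion (log-odds);
#'   controls the size of subnational gaps.
#' @param decline_mean,decline_sd Country annual decline rate (log-odds per
#'   year) mean and SD; negative draws give worsening countries.
#' @param unit_decline_sd Unit-level decline-rate dispersion.
#' @param noise_sd Observation noise SD in percentage points.
#' @param shocks Optional list of blocks, each a list with `year_start`,
#'   `year_end`, `frac` (affected unit fraction), `add_pp` (added no-DTP,
#'   pp) and optionally `countries`.
#' @param pop_meanlog,pop_sdlog Log-normal unit population parameters
#'   (populations constant over years).
#' @param n_exemplars 0 or 1; with 1, the first country is constructed to
#'   dominate both reduction dimensions (a designated exemplar for recovery
#'   tests).
#' @param exemplar_margin_pp Dominance margin for the designated exemplar:
#'   its noiseless reductions must exceed every other country's by at least
#'   this many percentage points on both dimensions, so recovery is a
#'   property of the design rather than of noise realisations (default 5).
#' @param seed Integer seed fixing the full output stream.
#' @return A validated list of class `zd_spec`.
#' @export
synthetic_spec <- function(n_countries = 56,
                           years = 2000:2019,
                           n_units_range = c(8, 800),
                           baseline_logit_mean = qlogis(0.20),
                           baseline_logit_sd = 0.9,
                           unit_logit_sd = 0.7,
                           decline_mean = 0.10,
                           decline_sd = 0.05,
                           unit_decline_sd = 0.02,
                           noise_sd = 0.5,
                           shocks = NULL,
                           pop_meanlog = 9,
                           pop_sdlog = 1,
                           n_exemplars = 0,
                           exemplar_margin_pp = 5,
                           seed = 1L) {
  spec <- list(
    n_countries = as.integer(n_countries), years = as.integer(years),
    n_units_range = as.integer(n_units_range),
    baseline_logit_mean = baseline_logit_mean,
    baseline_logit_sd = baseline_logit_sd,
    unit_logit_sd = unit_logit_sd,
    decline_mean = decline_mean, decline_sd = decline_sd,
    unit_decline_sd = unit_decline_sd, noise_sd = noise_sd,
    shocks = shocks, pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
    n_exemplars = as.integer(n_exemplars),
    exemplar_margin_pp = exemplar_margin_pp, seed = as.integer(seed)
  )
  if (spec$exemplar_margin_pp < 0 || !is.finite(spec$exemplar_margin_pp)) {
    stop_zd("exemplar_margin_pp must be finite and >= 0",
            "zd_validation_error")
  }
  disp <- c(spec$baseline_logit_sd, spec$unit_logit_sd, spec$decline_sd,
            spec$unit_decline_sd, spec$noise_sd, spec$pop_sdlog)
  if (any(disp < 0) || any(!is.finite(disp))) {
    stop_zd("dispersion parameters must be finite and >= 0",
            "zd_validation_error")
  }
  if (spec$n_countries < 1 || any(spec$n_units_range < 1) ||
      spec$n_units_range[1] > spec$n_units_range[2]) {
    stop_zd("need n_countries >= 1 and a valid n_units_range",
            "zd_validation_error")
  }
  if (!is.finite(spec$decline_mean) || !is.finite(spec$baseline_logit_mean)) {
    stop_zd("rate and baseline means must be finite", "zd_validation_error")
  }
  if (length(spec$years) < 2) {
    stop_zd("need at least two years", "zd_validation_error")
  }
  if (!spec$n_exemplars %in% c(0L, 1L)) {
    stop_zd("n_exemplars must be 0 or 1", "zd_validation_error")
  }
  structure(spec, class = "zd_spec")
}

clip_pct <- function(x) pmin(pmax(x, 0), 100)

#' Generate one country's unit-year panel
#'
#' Simulates every admin-2 unit of one country over the year range: unit
#' baselines and decline rates are drawn around the country parameters, the
#' noiseless logit-linear trajectory is evaluated per year, observation
#' noise is added on the percent scale, and values are clipped to
#' \[0, 100\] (clipping only guards noise excursions; the trajectory itself
#' is bounded by construction).
#'
#' @param country Country identifier to stamp on the rows.
#' @param n_units Number of admin-2 units.
#' @param baseline_logit Country mean baseline (log-odds of no-DTP
#'   proportion).
#' @param decline Country annual decline rate (log-odds/year).
#' @param years Year vector.
#' @param unit_logit_sd,unit_decline_sd,noise_sd,pop_meanlog,pop_sdlog,shocks
#'   See [synthetic_spec()].
#' @param seed Optional seed; when given, output is a pure function of the
#'   arguments.
#' @return Tibble with `country`, `admin1`, `admin2`, `year`, `no_dtp`
#'   (observed), `no_dtp_true` (noiseless, pre-shock), `population`.
#' @export
generate_country <- function(country, n_units, baseline_logit, decline, years,
                             unit_logit_sd = 0.7, unit_decline_sd = 0.02,
                             noise_sd = 0.5, pop_meanlog = 9, pop_sdlog = 1,
                             shocks = NULL, seed = NULL) {
  if (n_units < 1) stop_zd("n_units must be >= 1", "zd_validation_error")
  gen <- function() {
    b_u <- rnorm(n_units, baseline_logit, unit_logit_sd)
    r_u <- rnorm(n_units, decline, unit_decline_sd)
    pop <- round(rlnorm(n_units, pop_meanlog, pop_sdlog))
    admin2 <- sprintf("%s_U%03d", country, seq_len(n_units))
    admin1 <- sprintf("%s_A%02d", country, ceiling(seq_len(n_units) / 25))
    elapsed <- years - years[1]
    grid <- expand.grid(unit = seq_len(n_units), year = years,
                        KEEP.OUT.ATTRS = FALSE)
    truth <- plogis(b_u[grid$unit] - r_u[grid$unit] *
                      elapsed[match(grid$year, years)]) * 100
    obs <- truth + rnorm(nrow(grid), 0, noise_sd)
    if (!is.null(shocks)) {
      for (blk in shocks) {
        if (!is.null(blk$countries) && !country %in% blk$countries) next
        hit <- runif(n_units) < blk$frac
        in_window <- grid$year >= blk$year_start & grid$year <= blk$year_end
        obs <- obs + ifelse(hit[grid$unit] & in_window, blk$add_pp, 0)
      }
    }
    tibble::tibble(
      country = country,
      admin1 = admin1[grid$unit],
      admin2 = admin2[grid$unit],
      year = as.integer(grid$year),
      no_dtp = clip_pct(obs),
      no_dtp_true = truth,
      population = pop[grid$unit]
    )
  }
  out <- if (is.null(seed)) gen() else with_seed(seed, gen())
  dplyr::arrange(out, .data$admin2, .data$year)
}

# Noiseless national level and percentile gap at the endpoint years,
# computed from the latent trajectories (the designed truth).
true_endpoints <- function(country_panel) {
  years <- range(country_panel$year)
  ep <- function(yr) {
    v <- country_panel$no_dtp_true[country_panel$year == yr]
    c(national = mean(v), gap = subnational_gap(v)$gap)
  }
  s <- ep(years[1]); e <- ep(years[2])
  tibble::tibble(
    true_national_start = s["national"], true_national_end = e["national"],
    true_gap_start = s["gap"], true_gap_end = e["gap"],
    true_national_change = e["national"] - s["national"],
    true_gap_change = e["gap"] - s["gap"]
  )
}

#' Generate a full synthetic study: panel plus designed truth
#'
#' Draws country-level parameters from the spec, simulates every country
#' with [generate_country()], and emits (1) a coverage panel in the
#' [read_panel()] layout (`dtp1_coverage = 100 - no_dtp`) that passes
#' [validate_panel()], and (2) a truth table holding each country's latent
#' parameters and noiseless endpoint reductions.
#'
#' With `n_exemplars = 1` the first country is designated an exemplar: its
#' baseline and decline rate are set above the rest of the draw and the
#' decline is increased (deterministically) until its noiseless reductions
#' strictly dominate every other country on both dimensions, so ranking
#' pipelines can be checked for identity recovery.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `zd_synthetic`: `panel` (coverage panel),
#'   `truth` (one row per country), `spec`.
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "zd_spec"))
  with_seed(spec$seed, {
    n <- spec$n_countries
    countries <- sprintf("S%02d", seq_len(n))
    lo <- log(spec$n_units_range[1]); hi <- log(spec$n_units_range[2])
    n_units <- pmax(1L, as.integer(round(exp(runif(n, lo, hi)))))
    baseline <- rnorm(n, spec$baseline_logit_mean, spec$baseline_logit_sd)
    decline <- rnorm(n, spec$decline_mean, spec$decline_sd)
    unit_sds <- rep(spec$unit_logit_sd, n)
    if (spec$n_exemplars == 1L && n > 1) {
      # high (but unsaturated) starting level, widest unit spread, fastest
      # decline: large reductions in both the national level and the gap
      baseline[1] <- max(baseline[-1]) + 0.3
      decline[1] <- max(decline[-1]) + 3 * spec$decline_sd + 0.02
      unit_sds[1] <- spec$unit_logit_sd * 1.5
      n_units[1] <- max(n_units[1], 20L)
    }
    country_seeds <- sample.int(.Machine$integer.max - 1L, n)

    build <- function(i) {
      generate_country(
        countries[i], n_units[i], baseline[i], decline[i], spec$years,
        unit_logit_sd = unit_sds[i],
        unit_decline_sd = spec$unit_decline_sd,
        noise_sd = spec$noise_sd,
        pop_meanlog = spec$pop_meanlog, pop_sdlog = spec$pop_sdlog,
        shocks = spec$shocks, seed = country_seeds[i]
      )
    }
    panels <- lapply(seq_len(n), build)

    if (spec$n_exemplars == 1L && n > 1) {
      # enforce dominance of the designated exemplar's noiseless reductions
      # on both dimensions, by the spec margin (bounded deterministic
      # adjustment)
      mg <- spec$exemplar_margin_pp
      for (attempt in seq_len(25L)) {
        tr <- dplyr::bind_rows(lapply(panels, true_endpoints))
        dom <- tr$true_national_change[1] <
          min(tr$true_national_change[-1]) - mg &&
          tr$true_gap_change[1] < min(tr$true_gap_change[-1]) - mg
        if (dom) break
        # widen the exemplar's unit spread (raises its starting gap) and
        # speed its decline (drives both end-year measures toward zero)
        decline[1] <- decline[1] + 0.05
        unit_sds[1] <- unit_sds[1] + 0.1
        panels[[1]] <- build(1L)
      }
    }

    truth <- dplyr::bind_cols(
      tibble::tibble(
        country = countries, n_units = n_units,
        baseline_logit = baseline, decline = decline,
        designated_exemplar = spec$n_exemplars == 1L &
          seq_len(n) == 1L
      ),
      dplyr::bind_rows(lapply(panels, true_endpoints))
    )
    panel <- dplyr::bind_rows(panels)
    panel <- tibble::tibble(
      country = panel$country, admin1 = panel$admin1, admin2 = panel$admin2,
      year = panel$year,
      dtp1_coverage = 100 - panel$no_dtp,
      population = panel$population
    )
    validate_panel(panel, value = "dtp1_coverage")
    structure(list(panel = panel, truth = truth, spec = spec),
              class = "zd_synthetic")
  })
}
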