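test_that("subnational_gap handles degenerate and bad inputs", {
  expect_equal(subnational_gap(rep(12, 20))$gap, 0)
  expect_equal(subnational_gap(37.5)$gap, 0)
  expect_error(subnational_gap(numeric(0)), class = "zd_validation_error")
  expect_error(subnational_gap(c(NA_real_, NA_real_)),
               class = "zd_validation_error")
  expect_error(subnational_gap(1:5, lower = 0.9, upper = 0.1),
               class = "zd_validation_error")
})

test_that("subnational_gap matches the independent sort-based oracle", {
  set.seed(11)
  for (n in c(1, 2, 3, 7, 37, 100, 774)) {
    x <- runif(n, 0, 100)
    g <- subnational_gap(x)
    expect_equal(g$p5, oracle_quantile(x, 0.05), tolerance = 1e-9)
    expect_equal(g$p95, oracle_quantile(x, 0.95), tolerance = 1e-9)
    expect_equal(g$gap, oracle_gap(x), tolerance = 1e-9)
  }
})

test_that("gap is translation-equivariant, permutation-invariant, bounded", {
  set.seed(12)
  for (i in 1:20) {
    x <- runif(sample(2:200, 1), 0, 80)
    g <- subnational_gap(x)$gap
    expect_equal(subnational_gap(x + 10)$gap, g, tolerance = 1e-12)
    expect_equal(subnational_gap(sample(x))$gap, g, tolerance = 1e-12)
    expect_lte(g, max(x) - min(x))
    expect_gte(g, 0)
  }
})

test_that("population-weighted quantiles respond to weights sensibly", {
  x <- c(10, 20, 30, 40)
  even <- subnational_gap(x, weights = rep(1, 4))
  skew <- subnational_gap(x, weights = c(100, 1, 1, 100))
  expect_gte(skew$gap, even$gap)  # mass at the extremes widens the gap
  expect_error(subnational_gap(x, weights = c(-1, 1, 1, 1)),
               class = "zd_validation_error")
})

test_that("national_series supports all three modes", {
  panel <- tibble::tibble(
    country = "AAA", admin1 = "a", admin2 = c("u1", "u2"),
    year = 2000L, no_dtp = c(10, 30), population = c(1, 3)
  )
  expect_equal(national_series(panel, "pop_weighted")$national_no_dtp, 25.0)
  expect_equal(national_series(panel, "unweighted_mean")$national_no_dtp, 20.0)
  single <- panel[1, ]
  expect_equal(national_series(single, "unweighted_mean")$national_no_dtp, 10)
  expect_equal(national_series(single, "pop_weighted")$national_no_dtp, 10)
  nat <- tibble::tibble(country = "AAA", year = 2000L, national_no_dtp = 51.9)
  expect_equal(national_series(panel, "provided", nat)$national_no_dtp, 51.9)
  expect_error(national_series(panel, "provided"), class = "zd_schema_error")
  expect_error(
    national_series(panel, "provided",
                    tibble::tibble(country = "BBB", year = 2000L,
                                   national_no_dtp = 1)),
    class = "zd_validation_error"
  )
  zero_pop <- dplyr::mutate(panel, population = 0)
  expect_error(national_series(zero_pop, "pop_weighted"),
               class = "zd_validation_error")
})

test_that("provided-mode national series passes fixture values through", {
  m <- table2_metrics()
  nat <- m[, c("country", "year", "national_no_dtp")]
  panel <- tibble::tibble(country = m$country, admin1 = NA, admin2 = "u1",
                          year = m$year, no_dtp = 0)
  out <- national_series(panel, "provided", nat)
  joined <- dplyr::left_join(nat, out, by = c("country", "year"))
  expect_equal(joined$national_no_dtp.y, joined$national_no_dtp.x)
})

test_that("change_metrics computes both dimensions with the sign convention", {
  ch <- change_metrics(table2_metrics())
  drc <- ch[ch$country == "Dem Rep of the Congo" & ch$dimension == "national", ]
  expect_equal(drc$absolute_change, -45.0)
  flat <- tibble::tibble(country = "A", year = c(2000L, 2019L),
                         national_no_dtp = 20, gap = c(20, 10))
  fc <- change_metrics(flat)
  expect_equal(fc$absolute_change[fc$dimension == "national"], 0)
  expect_equal(fc$relative_change[fc$dimension == "national"], 0)
  expect_equal(fc$relative_change[fc$dimension == "subnational_gap"], -50.0)
})

test_that("relative change is undefined at zero start and scale-invariant", {
  m <- tibble::tibble(country = "A", year = c(2000L, 2019L),
                      national_no_dtp = c(0, 5), gap = c(10, 5))
  ch <- change_metrics(m)
  expect_true(is.na(ch$relative_change[ch$dimension == "national"]))
  set.seed(3)
  for (k in c(0.5, 2, 17)) {
    s <- runif(1, 1, 50); e <- runif(1, 1, 50)
    base <- tibble::tibble(country = "A", year = c(2000L, 2019L),
                           national_no_dtp = c(s, e), gap = c(s, e))
    scaled <- dplyr::mutate(base, national_no_dtp = national_no_dtp * k,
                            gap = gap * k)
    expect_equal(change_metrics(scaled)$relative_change,
                 change_metrics(base)$relative_change, tolerance = 1e-12)
  }
})

test_that("countries missing an endpoint year are dropped with a warning", {
  m <- tibble::tibble(country = c("A", "A", "B"),
                      year = c(2000L, 2019L, 2000L),
                      national_no_dtp = c(10, 5, 8), gap = c(5, 2, 4))
  expect_warning(ch <- change_metrics(m), "B")
  expect_setequal(unique(ch$country), "A")
})

test_that("classify_progress reproduces the published four-way partition", {
  q <- classify_progress(change_metrics(table2_metrics()))
  counts <- progress_counts(q)
  expect_equal(counts$n[counts$category == "both_reduced"], 44L)
  expect_setequal(
    q$country[q$category == "both_increased"],
    c("Benin", "Kenya", "Guinea", "Papua New Guinea", "Uzbekistan")
  )
  expect_setequal(
    q$country[q$category == "national_only_reduced"],
    c("Congo", "Tajikistan", "Djibouti", "Central African Rep",
      "Sao Tome and Principe")
  )
  expect_setequal(q$country[q$category == "gap_only_reduced"],
                  c("Haiti", "Myanmar"))
  expect_equal(sum(counts$n), 56L)
})

test_that("zero change counts as not reduced", {
  m <- tibble::tibble(country = c("A", "A"), year = c(2000L, 2019L),
                      national_no_dtp = 10, gap = 5)
  q <- classify_progress(change_metrics(m))
  expect_equal(as.character(q$category), "both_increased")
})

test_that("units_gap_correlation flags degenerate inputs and recovers structure", {
  make_panel <- function(n_units_per_country, gap_scale) {
    rows <- lapply(seq_along(n_units_per_country), function(i) {
      n <- n_units_per_country[i]
      tibble::tibble(
        country = sprintf("C%02d", i), admin1 = "a",
        admin2 = sprintf("u%03d", seq_len(n)), year = 2000L,
        no_dtp = 50 + gap_scale[i] * seq(-0.5, 0.5, length.out = n)
      )
    })
    dplyr::bind_rows(rows)
  }
  # identical unit counts -> zero variance -> undefined
  p0 <- make_panel(rep(10, 5), rep(10, 5))
  expect_warning(r0 <- units_gap_correlation(p0, 2000), "zero variance")
  expect_true(is.na(r0))
  # gap constructed proportional to unit count -> r near 1
  n_units <- c(10, 50, 100, 200, 400)
  p1 <- make_panel(n_units, n_units / 10)
  r1 <- units_gap_correlation(p1, 2000)
  expect_gt(as.numeric(r1), 0.99)
  # independently drawn gaps -> |r| small at larger n
  set.seed(9)
  n <- sample(10:100, 40, replace = TRUE)
  p2 <- make_panel(n, runif(40, 5, 30))
  expect_lt(abs(as.numeric(units_gap_correlation(p2, 2000))), 0.5)
  expect_error(units_gap_correlation(p1, 1990), class = "zd_validation_error")
})

test_that("country_year_metrics assembles national, percentiles and gap", {
  study <- generate_study(small_spec(n_countries = 3, seed = 5))
  panel <- to_no_dtp(study$panel)
  m <- suppressMessages(country_year_metrics(panel))
  expect_equal(nrow(m), 3L * 20L)
  expect_true(all(m$p5 <= m$p95))
  expect_true(all(m$gap >= 0))
  expect_true(all(m$national_no_dtp >= 0 & m$national_no_dtp <= 100))
  # single-unit country: gap defined as 0, with a notice
  single <- tibble::tibble(country = "S", admin1 = "a", admin2 = "u1",
                           year = c(2000L, 2019L), no_dtp = c(30, 10))
  expect_message(ms <- country_year_metrics(single), "single-unit")
  expect_equal(ms$gap, c(0, 0))
})
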