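test_that("baseline_distance covers all three dimensions", {
  a <- list(national_no_dtp = 36.4, gap = 47.8)
  b <- list(national_no_dtp = 51.9, gap = 46.8)
  expect_equal(baseline_distance(a, a, "joint"), 0)
  expect_equal(baseline_distance(a, b, "gap"), 1.0)
  expect_equal(baseline_distance(a, b, "national"), 15.5)
  nga <- list(national_no_dtp = 55.5, gap = 71.7)
  eth <- list(national_no_dtp = 63.4, gap = 47.9)
  expect_equal(baseline_distance(nga, eth, "joint"),
               sqrt((63.4 - 55.5)^2 + (47.9 - 71.7)^2))
  expect_error(baseline_distance(list(national_no_dtp = 1, gap = NA), b, "gap"),
               class = "zd_validation_error")
})

test_that("match_neighbor picks the minimal-distance candidate", {
  m <- toy_metrics()
  res <- match_neighbor("Alpha", c("Bravo", "Charlie", "Delta"), m,
                        dimension = "national")
  expect_equal(res$matched, "Bravo")  # |32-30| beats |50-30| and |10-30|
  expect_equal(res$distance, 2)
  expect_equal(res$divergence_national, 20 - 10)
  expect_equal(res$divergence_gap, 15 - 5)
  # pool of one: that candidate regardless of distance
  solo <- match_neighbor("Alpha", "Charlie", m, dimension = "gap")
  expect_equal(solo$matched, "Charlie")
  expect_error(match_neighbor("Alpha", "Alpha", m),
               class = "zd_validation_error")
})

test_that("match_neighbor is invariant to candidate pool ordering", {
  m <- toy_metrics()
  pool <- c("Bravo", "Charlie", "Delta")
  for (dim in c("national", "gap", "joint")) {
    base <- match_neighbor("Alpha", pool, m, dimension = dim)
    for (i in 1:3) {
      expect_equal(
        match_neighbor("Alpha", sample(pool), m, dimension = dim)$matched,
        base$matched
      )
    }
  }
})

test_that("standardized joint matching is invariant to rescaling one axis", {
  m <- toy_metrics()
  pool <- c("Bravo", "Charlie", "Delta")
  base <- match_neighbor("Alpha", pool, m, dimension = "joint",
                         standardize = TRUE)
  scaled <- dplyr::mutate(m, gap = gap * 25)
  res <- match_neighbor("Alpha", pool, scaled, dimension = "joint",
                        standardize = TRUE)
  expect_equal(res$matched, base$matched)
})

test_that("divergence_report pairs trajectories year by year", {
  m <- toy_metrics()
  self <- divergence_report("Alpha", "Alpha", m)
  expect_true(all(self$diff_national == 0) && all(self$diff_gap == 0))
  # constructed constant offset propagates to every year
  shifted <- dplyr::mutate(m[m$country == "Alpha", ],
                           country = "AlphaPlus",
                           national_no_dtp = national_no_dtp + 3,
                           gap = gap + 1.5)
  rep2 <- divergence_report("Alpha", "AlphaPlus",
                            dplyr::bind_rows(m, shifted))
  expect_equal(rep2$diff_national, c(3, 3))
  expect_equal(rep2$diff_gap, c(1.5, 1.5))
  expect_error(
    divergence_report("Alpha", "Bravo", m, years = 2005),
    class = "zd_validation_error"
  )
})

test_that("hub matching without replacement reproduces the published pairings", {
  m <- table2_metrics()
  exemplars <- c("Dem Rep of the Congo", "Ethiopia", "India",
                 "Bangladesh", "Burundi")
  res <- match_learning_hubs(
    m, targets = c("Nigeria", "Mali", "Uganda"), pool = exemplars,
    dimensions = c("joint", "gap", "national")
  )
  expect_equal(res$matched,
               c("Ethiopia", "Dem Rep of the Congo", "Burundi"))
  expect_equal(res$distance[2], 1.0)   # |47.8 - 46.8|
  expect_equal(res$distance[3], 3.5)   # |21.9 - 18.4|
  # Uganda vs Burundi end-year national levels: 6.7% and 2.3%
  div <- divergence_report("Uganda", "Burundi", m)
  expect_equal(div$match_national[div$year == 2019], 2.3)
  expect_equal(div$target_national[div$year == 2019], 6.7)
})

test_that("with replacement every target sees the full pool", {
  m <- table2_metrics()
  exemplars <- c("Dem Rep of the Congo", "Ethiopia", "India",
                 "Bangladesh", "Burundi")
  res <- match_learning_hubs(
    m, targets = c("Nigeria", "Mali"), pool = exemplars,
    dimensions = "gap", without_replacement = FALSE
  )
  # on rounded printed gaps Ethiopia (47.9) is marginally nearer Mali (47.8)
  expect_equal(res$matched[res$target == "Mali"], "Ethiopia")
})

test_that("admin-1 aggregates work as entities with no code-path changes", {
  study <- generate_study(small_spec(n_countries = 2, n_units_range = c(30, 60),
                                     seed = 8))
  panel <- to_no_dtp(study$panel)
  a1 <- admin1_metrics(panel, country = panel$country[1])
  expect_true(all(c("admin1", "year", "national_no_dtp", "gap") %in% names(a1)))
  entities <- unique(a1$admin1)
  expect_gte(length(entities), 2L)
  res <- match_neighbor(entities[1], entities[-1], a1, id = "admin1")
  expect_true(res$matched %in% entities[-1])
  div <- divergence_report(entities[1], res$matched, a1, id = "admin1")
  expect_equal(nrow(div), 20L)
})
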