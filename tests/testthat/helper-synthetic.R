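# Small synthetic study specs sized for fast tests.
small_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_countries = 6, n_units_range = c(8, 40),
                   years = 2000:2019, seed = 42L)
  do.call(synthetic_spec, utils::modifyList(defaults, args))
}

# Tiny hand-built no-DTP metrics table for neighborhood tests.
toy_metrics <- function() {
  tibble::tibble(
    country = rep(c("Alpha", "Bravo", "Charlie", "Delta"), each = 2),
    year = rep(c(2000L, 2019L), 4),
    national_no_dtp = c(30, 10, 32, 20, 50, 40, 10, 5),
    gap = c(20, 5, 24, 15, 45, 30, 8, 2)
  )
}
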