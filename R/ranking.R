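#' Ordinal ranks for one reduction dimension
#'
#' Ranks change values so that the most negative change (largest reduction)
#' receives rank 1 and the largest increase receives rank N. Ties share the
#' average ("fractional") rank by default, which keeps each rank column
#' summing to N(N+1)/2; competition ("min") ranking is available.
#'
#' @param x Numeric change values (one per country).
#' @param ties `"average"` (default) or `"min"`.
#' @return Numeric ranks, same length as `x`.
#' @export
#' @examples
#' rank_dimension(c(-5, -3, 2))   # 1 2 3
#' rank_dimension(c(-5, -5, 2))   # 1.5 1.5 3
rank_dimension <- function(x, ties = c("average", "min")) {
  ties <- match.arg(ties)
  if (!length(x)) stop_zd("cannot rank an empty vector", "zd_validation_error")
  rank(x, ties.method = ties, na.last = "keep")
}

#' Dual-dimension ranking table for one progress track
#'
#' Ranks every country on each geographic dimension (national reduction,
#' subnational-gap reduction) for the chosen progress track, then averages
#' the two ranks with equal weight. On the relative track, countries whose
#' relative change is undefined on either dimension (start value 0) are
#' excluded with a message rather than ranked last.
#'
#' @param changes Output of [change_metrics()].
#' @param track `"absolute"` (percentage-point changes) or `"relative"`
#'   (percentage changes).
#' @param ties Tie policy passed to [rank_dimension()].
#' @return Tibble with `country`, `track`, `change_national`, `change_gap`,
#'   `rank_national`, `rank_gap`, `mean_rank`, sorted by `mean_rank`.
#' @export
ranking_table <- function(changes, track = c("absolute", "relative"),
                          ties = c("average", "min")) {
  track <- match.arg(track)
  ties <- match.arg(ties)
  col <- if (track == "absolute") "absolute_change" else "relative_change"
  wide <- tidyr::pivot_wider(
    changes[, c("country", "dimension", col)],
    names_from = "dimension", values_from = dplyr::all_of(col)
  )
  undef <- wide$country[is.na(wide$national) | is.na(wide$subnational_gap)]
  if (length(undef)) {
    inform(sprintf("excluded from the %s track (undefined change): %s",
                   track, paste(undef, collapse = ", ")))
    wide <- wide[!wide$country %in% undef, , drop = FALSE]
  }
  if (!nrow(wide)) stop_zd("no rankable countries", "zd_validation_error")
  out <- tibble::tibble(
    country = wide$country,
    track = track,
    change_national = wide$national,
    change_gap = wide$subnational_gap,
    rank_national = rank_dimension(wide$national, ties),
    rank_gap = rank_dimension(wide$subnational_gap, ties)
  )
  out$mean_rank <- (out$rank_national + out$rank_gap) / 2
  dplyr::arrange(out, .data$mean_rank, .data$change_national, .data$country)
}

#' Mean of the two dimension ranks
#'
#' Equal-weight aggregation of a country's national and subnational-gap
#' ranks, the score on which exemplars are selected.
#'
#' @param rank_national,rank_gap Numeric ranks.
#' @return `(rank_national + rank_gap) / 2`.
#' @export
mean_rank <- function(rank_national, rank_gap) {
  (rank_national + rank_gap) / 2
}

#' Select exemplar countries from a ranking table
#'
#' The `k` countries with the smallest mean rank are flagged as potential
#' exemplars ("positive outliers"). Mean-rank ties are broken
#' deterministically by larger national reduction (more negative
#' `change_national`), then alphabetically.
#'
#' @param ranking Output of [ranking_table()].
#' @param k Number of exemplars; defaults to 3 on the absolute track and 2
#'   on the relative track, the counts singled out in the published
#'   analysis.
#' @return The ranking table with an added logical `exemplar` column, sorted
#'   so the selected rows come first.
#' @export
select_exemplars <- function(ranking, k = NULL) {
  if (is.null(k)) {
    k <- if (ranking$track[1] == "absolute") 3L else 2L
  }
  if (k > nrow(ranking)) {
    stop_zd(sprintf("k = %d exceeds the %d ranked countries",
                    k, nrow(ranking)), "zd_validation_error")
  }
  ordered <- dplyr::arrange(ranking, .data$mean_rank, .data$change_national,
                            .data$country)
  ordered$exemplar <- seq_len(nrow(ordered)) <= k
  ordered
}
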