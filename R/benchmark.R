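#' Published signal-accuracy benchmark
#'
#' Per-joint normalised DTW distances and percentage errors reported for a
#' 78-sample markerless gait study comparing the prior-substitution filter
#' (KF1+FDF), the posterior-substitution filter (KF2+FDF) and the unfiltered
#' original signals against gold-standard motion capture, split by far/near
#' side and knee/hip joint. Shipped so the aggregation conventions of the
#' metrics module can be exercised on realistic magnitudes.
#'
#' @return Tibble with columns `method`, `side`, `joint`, `dtw`, `pe`.
#' @export
signal_accuracy_benchmark <- function() {
  path <- system.file("extdata", "signal_accuracy_summary.csv",
                      package = "posegait", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Aggregate per-joint accuracy values
#'
#' The reporting convention for per-joint accuracy tables: a method's
#' "average" DTW and PE are the plain means of its four per-joint entries
#' (far/near x knee/hip).
#'
#' @param tab Tibble as returned by [signal_accuracy_benchmark()].
#' @return Tibble with one row per method: `method`, `dtw`, `pe`.
#' @export
aggregate_signal_accuracy <- function(tab) {
  tab |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(dtw = mean(.data$dtw), pe = mean(.data$pe),
                     .groups = "drop")
}
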