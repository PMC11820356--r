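#' Bundled paired RF comparison data
#'
#' Ten volunteers assessed by both the stepped-and-ranked and the
#' sliding-sweep method (breaths/min). Used by the worked examples and
#' the agreement-statistics tests.
#'
#' @return A data.frame with columns `participant`, `sliding`, `stepped`.
#' @export
example_rf_comparison <- function() {
  path <- system.file("extdata", "method_comparison_rf.csv",
                      package = "rfbreathe", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#")
}

#' Bundled single-participant metric-ranking example
#'
#' Synthetic metric values over five paced frequencies whose per-metric
#' descending orderings reproduce a published worked example of the
#' stepped-and-ranked selection (candidate set \{4.5, 5\}, amplitude
#' tie-break to 4.5 breaths/min).
#'
#' @return A data.frame of class `frequency_trials` with columns `freq`,
#'   `mean_amp`, `lf_ratio`, `plv`, usable by [stepped_and_ranked()].
#' @export
example_rank_trials <- function() {
  path <- system.file("extdata", "ranking_example.csv",
                      package = "rfbreathe", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#")
  class(df) <- c("frequency_trials", "data.frame")
  df
}
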