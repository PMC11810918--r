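#' Published per-cluster summary statistics of the reference cohort
#'
#' The printed per-cluster summary table of the Ugandan PWH cohort the
#' synthetic generator is calibrated to: cluster sizes, mean (SD) of the
#' three mental-health totals, CTQ physical/sexual-abuse category counts,
#' and demographic summaries, plus the total-sample row. Used for internal
#' consistency checks (prevalence-weighted cluster means vs the total-sample
#' means) and for referent-cluster tests computed from summary statistics.
#'
#' @return Data frame with one row per cluster (`C1`..`C4`) and a `total`
#'   row.
#' @export
reference_cluster_summary <- function() {
  path <- system.file("extdata", "reference_cluster_summary.csv",
                      package = "mhpheno", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
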