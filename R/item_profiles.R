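# Item-level cluster profiles and score-distribution exports.

.instrument_prefixes <- function() {
  c(PHQ9 = "phq9", BAI = "bai", PCLC = "pclc",
    CTQ_PA = "ctq_pa", CTQ_SA = "ctq_sa")
}

#' Per-cluster item-level mean profiles
#'
#' Computes, for every (instrument, item, cluster) triple, the arithmetic
#' mean response and the endorsement rate (proportion of responses above the
#' item minimum). Empty clusters are omitted with a warning.
#'
#' @param cohort Cohort data frame with item columns (`<instrument>_item<k>`).
#' @param cluster Integer or character cluster assignment per row (noise `0`
#'   rows are profiled under cluster `0` if present).
#' @param instruments Instruments to profile (default all five).
#' @return Data frame with columns `instrument`, `item`, `item_key`,
#'   `cluster`, `n`, `mean_response`, `endorsement_rate`.
#' @export
profile_items <- function(cohort, cluster,
                          instruments = names(.instrument_prefixes())) {
  stopifnot(nrow(cohort) == length(cluster))
  ids <- if (is.factor(cluster)) levels(cluster) else sort(unique(cluster))
  empty <- ids[!ids %in% unique(as.vector(cluster))]
  if (length(empty) > 0) {
    warning("omitting empty cluster(s): ", paste(empty, collapse = ", "))
    ids <- setdiff(ids, empty)
  }
  out <- list()
  for (ins in instruments) {
    spec <- instrument_spec(ins)
    prefix <- .instrument_prefixes()[[ins]]
    for (item in seq_len(spec$n_items)) {
      col <- paste0(prefix, "_item", item)
      if (!col %in% names(cohort)) next
      x <- cohort[[col]]
      for (id in ids) {
        sel <- cluster == id
        if (!any(sel)) next
        out[[length(out) + 1L]] <- data.frame(
          instrument = ins, item = item, item_key = col, cluster = id,
          n = sum(sel), mean_response = mean(x[sel]),
          endorsement_rate = mean(x[sel] > spec$item_min),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Long-format total-score export
#'
#' One row per participant per instrument with the total score and cluster
#' assignment: the tidy data behind strip/score-distribution plots. Loss-less:
#' re-aggregating the export reproduces the per-cluster summaries.
#'
#' @param scored Scored cohort (needs `bai_total`, `phq9_total`, `pclc_total`).
#' @param cluster Cluster assignment per row.
#' @param id Optional participant ids (default `scored$id` or row index).
#' @return Data frame with `participant`, `instrument`, `total`, `cluster`;
#'   `nrow = n * 3`.
#' @export
export_strip_data <- function(scored, cluster, id = NULL) {
  stopifnot(nrow(scored) == length(cluster))
  if (is.null(id)) id <- if (!is.null(scored$id)) scored$id else seq_len(nrow(scored))
  cols <- c(BAI = "bai_total", PHQ9 = "phq9_total", PCLC = "pclc_total")
  out <- do.call(rbind, lapply(names(cols), function(ins) {
    data.frame(participant = id, instrument = ins,
               total = scored[[cols[[ins]]]], cluster = cluster,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
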