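#' Instrument specifications
#'
#' Returns the item-count and item-range specification of one of the five
#' supported self-report instruments / subscales:
#'
#' * `PHQ9` — Patient Health Questionnaire-9, 9 items scored 0–3 (total 0–27).
#' * `BAI` — Beck Anxiety Inventory, 21 items scored 0–3 (total 0–63).
#' * `PCLC` — PTSD Checklist–Civilian Version, 17 items scored 1–5 (total 17–85).
#' * `CTQ_PA`, `CTQ_SA` — Childhood Trauma Questionnaire physical- and
#'   sexual-abuse subscales, 5 items each scored 1–5 (totals 5–25).
#'
#' @param name One of `"PHQ9"`, `"BAI"`, `"PCLC"`, `"CTQ_PA"`, `"CTQ_SA"`.
#' @return An object of class `instrument_spec`: a list with elements
#'   `name`, `n_items`, `item_min`, `item_max`, `total_min`, `total_max`.
#' @examples
#' instrument_spec("PHQ9")
#' @export
instrument_spec <- function(name = c("PHQ9", "BAI", "PCLC", "CTQ_PA", "CTQ_SA")) {
  name <- match.arg(name)
  spec <- switch(name,
    PHQ9   = list(n_items = 9L,  item_min = 0L, item_max = 3L),
    BAI    = list(n_items = 21L, item_min = 0L, item_max = 3L),
    PCLC   = list(n_items = 17L, item_min = 1L, item_max = 5L),
    CTQ_PA = list(n_items = 5L,  item_min = 1L, item_max = 5L),
    CTQ_SA = list(n_items = 5L,  item_min = 1L, item_max = 5L)
  )
  spec$name <- name
  spec$total_min <- spec$n_items * spec$item_min
  spec$total_max <- spec$n_items * spec$item_max
  structure(spec, class = "instrument_spec")
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(sprintf("<instrument_spec> %s: %d items in [%d, %d], total in [%d, %d]\n",
              x$name, x$n_items, x$item_min, x$item_max, x$total_min, x$total_max))
  invisible(x)
}

#' Names of the supported instruments
#' @return Character vector of instrument names.
#' @export
instrument_names <- function() c("PHQ9", "BAI", "PCLC", "CTQ_PA", "CTQ_SA")

#' Score an instrument from item-level responses
#'
#' Sums the item responses of one participant after validating length and
#' per-item range against the instrument specification. Missing items are
#' handled according to `missing`:
#'
#' * `"fail"` (default) — any missing item yields `NA` (the participant is
#'   excluded from the affected score);
#' * `"prorate"` — if at most one item is missing it is imputed with the
#'   rounded mean of the observed items; more than one missing item yields `NA`.
#'
#' @param responses Numeric vector of item responses, in item order.
#' @param spec An [instrument_spec()].
#' @param missing `"fail"` or `"prorate"`.
#' @return Integer total score (or `NA_integer_` under the missing policy).
#' @examples
#' score_instrument(rep(0, 9), instrument_spec("PHQ9"))
#' score_instrument(rep(5, 17), instrument_spec("PCLC"))
#' @export
score_instrument <- function(responses, spec, missing = c("fail", "prorate")) {
  missing <- match.arg(missing)
  stopifnot(inherits(spec, "instrument_spec"))
  if (length(responses) != spec$n_items) {
    stop(sprintf("%s expects %d items, got %d", spec$name, spec$n_items,
                 length(responses)), call. = FALSE)
  }
  obs <- !is.na(responses)
  bad <- which(obs & (responses < spec$item_min | responses > spec$item_max |
                        responses != floor(responses)))
  if (length(bad) > 0) {
    stop(sprintf("%s item %d response %s outside [%d, %d]", spec$name, bad[1],
                 format(responses[bad[1]]), spec$item_min, spec$item_max),
         call. = FALSE)
  }
  n_miss <- sum(!obs)
  if (n_miss == 0L) return(as.integer(sum(responses)))
  if (missing == "prorate" && n_miss == 1L && sum(obs) > 0L) {
    imputed <- round(mean(responses[obs]))
    imputed <- min(max(imputed, spec$item_min), spec$item_max)
    return(as.integer(sum(responses[obs]) + imputed))
  }
  NA_integer_
}

# Severity band cutoffs (lower bounds of each band). Standard published bands;
# exposed so alternates can be swapped in.
#' Default severity-band cutoffs
#'
#' Lower bounds of the standard severity bands for the PHQ-9 and the BAI,
#' and the PCL-C screening threshold for possible PTSD.
#'
#' @return Named list with `PHQ9`, `BAI` (named integer vectors of band lower
#'   bounds) and `PCLC_ptsd_threshold`.
#' @export
default_band_cutoffs <- function() {
  list(
    PHQ9 = c(minimal = 0L, mild = 5L, moderate = 10L,
             moderately_severe = 15L, severe = 20L),
    BAI = c(minimal = 0L, mild = 8L, moderate = 16L, severe = 26L),
    PCLC_ptsd_threshold = 33L
  )
}

#' Map a total score to its severity band
#'
#' @param total Integer total score(s).
#' @param instrument `"PHQ9"` or `"BAI"`.
#' @param cutoffs Band cutoffs as returned by [default_band_cutoffs()].
#' @return Ordered factor of severity bands, one per total.
#' @examples
#' band_severity(0, "PHQ9")
#' band_severity(27, "PHQ9")
#' @export
band_severity <- function(total, instrument = c("PHQ9", "BAI"),
                          cutoffs = default_band_cutoffs()) {
  instrument <- match.arg(instrument)
  spec <- instrument_spec(instrument)
  ok <- is.na(total) | (total >= spec$total_min & total <= spec$total_max)
  if (!all(ok)) {
    stop(sprintf("%s total %s outside [%d, %d]", instrument,
                 format(total[!ok][1]), spec$total_min, spec$total_max),
         call. = FALSE)
  }
  cuts <- cutoffs[[instrument]]
  idx <- findInterval(total, cuts)
  factor(names(cuts)[idx], levels = names(cuts), ordered = TRUE)
}

#' Default CTQ subscale category cutoffs
#'
#' Standard 4-level severity cutoffs for the physical-abuse (PA) and
#' sexual-abuse (SA) subscales, collapsed to three levels by merging the
#' moderate and severe bands. Values are the lower bounds of the
#' low-to-moderate and moderate-to-extreme categories.
#'
#' @return Named list with `PA` and `SA`, each `c(low_moderate=, moderate_extreme=)`.
#' @export
default_ctq_cutoffs <- function() {
  list(PA = c(low_moderate = 8L, moderate_extreme = 10L),
       SA = c(low_moderate = 6L, moderate_extreme = 8L))
}

#' CTQ category labels (3 levels, ordered)
#' @return Character vector of the three category labels.
#' @export
ctq_levels <- function() c("none_minimal", "low_moderate", "moderate_extreme")

#' Categorize a CTQ subscale total into three adversity levels
#'
#' @param subscale_total Integer total(s) in \[5, 25\].
#' @param subscale `"PA"` or `"SA"`.
#' @param cutoffs As returned by [default_ctq_cutoffs()].
#' @return Ordered factor with levels [ctq_levels()].
#' @examples
#' categorize_ctq(5, "SA")
#' categorize_ctq(25, "SA")
#' @export
categorize_ctq <- function(subscale_total, subscale = c("PA", "SA"),
                           cutoffs = default_ctq_cutoffs()) {
  subscale <- match.arg(subscale)
  ok <- is.na(subscale_total) | (subscale_total >= 5 & subscale_total <= 25)
  if (!all(ok)) {
    stop(sprintf("CTQ %s total %s outside [5, 25]", subscale,
                 format(subscale_total[!ok][1])), call. = FALSE)
  }
  cuts <- c(5L, cutoffs[[subscale]])
  idx <- findInterval(subscale_total, cuts)
  factor(ctq_levels()[idx], levels = ctq_levels(), ordered = TRUE)
}

#' Score a cohort table
#'
#' Takes a wide cohort table with item-level response columns named
#' `<instrument>_item<k>` (lower-case instrument prefix, e.g. `phq9_item1`,
#' `bai_item21`, `pclc_item17`, `ctq_pa_item5`, `ctq_sa_item1`) and appends
#' instrument totals, severity bands, the PTSD screening flag and CTQ
#' adversity categories.
#'
#' Appended columns: `phq9_total`, `bai_total`, `pclc_total`, `ctq_pa_total`,
#' `ctq_sa_total`, `phq9_band`, `bai_band`, `ptsd_flag`, `ctq_pa_cat`,
#' `ctq_sa_cat`.
#'
#' @param cohort Data frame with the item columns.
#' @param missing Missing-item policy passed to [score_instrument()].
#' @param band_cutoffs See [default_band_cutoffs()].
#' @param ctq_cutoffs See [default_ctq_cutoffs()].
#' @return The cohort with scoring columns appended.
#' @export
score_cohort <- function(cohort, missing = c("fail", "prorate"),
                         band_cutoffs = default_band_cutoffs(),
                         ctq_cutoffs = default_ctq_cutoffs()) {
  missing <- match.arg(missing)
  prefixes <- c(PHQ9 = "phq9", BAI = "bai", PCLC = "pclc",
                CTQ_PA = "ctq_pa", CTQ_SA = "ctq_sa")
  totals <- list()
  for (ins in names(prefixes)) {
    spec <- instrument_spec(ins)
    cols <- paste0(prefixes[[ins]], "_item", seq_len(spec$n_items))
    miss_cols <- setdiff(cols, names(cohort))
    if (length(miss_cols) > 0) {
      stop(sprintf("missing item columns for %s: %s", ins,
                   paste(miss_cols, collapse = ", ")), call. = FALSE)
    }
    mat <- as.matrix(cohort[, cols, drop = FALSE])
    totals[[prefixes[[ins]]]] <- vapply(
      seq_len(nrow(mat)),
      function(i) score_instrument(mat[i, ], spec, missing = missing),
      integer(1)
    )
  }
  cohort$phq9_total <- totals$phq9
  cohort$bai_total <- totals$bai
  cohort$pclc_total <- totals$pclc
  cohort$ctq_pa_total <- totals$ctq_pa
  cohort$ctq_sa_total <- totals$ctq_sa
  cohort$phq9_band <- band_severity(cohort$phq9_total, "PHQ9", band_cutoffs)
  cohort$bai_band <- band_severity(cohort$bai_total, "BAI", band_cutoffs)
  cohort$ptsd_flag <- !is.na(cohort$pclc_total) &
    cohort$pclc_total >= band_cutoffs$PCLC_ptsd_threshold
  cohort$ctq_pa_cat <- categorize_ctq(cohort$ctq_pa_total, "PA", ctq_cutoffs)
  cohort$ctq_sa_cat <- categorize_ctq(cohort$ctq_sa_total, "SA", ctq_cutoffs)
  cohort
}
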