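# Synthetic-cohort generator. Emulates a reference cohort of 277 Ugandan
# adults with virally suppressed HIV: four latent mental-health phenotypes
# (PTSD, anxiety, mixed anxiety/depression, minimal symptom) with published
# per-cluster score distributions, childhood-adversity category frequencies,
# demographics and covariate endorsement rates.

#' Latent phenotype identifiers of the synthetic cohort
#' @return Character vector `C1` (PTSD), `C2` (anxiety), `C3` (mixed
#'   anxiety/depression), `C4` (minimal symptom).
#' @export
phenotype_ids <- function() c("C1", "C2", "C3", "C4")

# pmf of clamp(round(N(mu, sigma))) on integers lo..hi
.discnorm_pmf <- function(mu, sigma, lo, hi) {
  k <- lo:hi
  if (sigma <= 0) {
    p <- as.numeric(k == min(max(round(mu), lo), hi))
    return(stats::setNames(p, k))
  }
  up <- stats::pnorm(k + 0.5, mu, sigma)
  lo_p <- stats::pnorm(k - 0.5, mu, sigma)
  p <- up - lo_p
  p[1] <- up[1]                 # all mass below lo+0.5 collapses to lo
  p[length(p)] <- 1 - lo_p[length(p)]
  stats::setNames(p, k)
}

# Latent mean calibrated so the clamped, discretized draw has the target mean.
.calibrate_discnorm_mu <- function(target_mean, sigma, lo, hi) {
  if (target_mean < lo || target_mean > hi) {
    stop(sprintf("infeasible target mean %.3f for range [%d, %d]",
                 target_mean, lo, hi), call. = FALSE)
  }
  if (sigma <= 0) return(target_mean)
  f <- function(mu) sum((lo:hi) * .discnorm_pmf(mu, sigma, lo, hi)) - target_mean
  lower <- lo - 6 * sigma - 1
  upper <- hi + 6 * sigma + 1
  stats::uniroot(f, c(lower, upper), tol = 1e-9)$root
}

# Seeded draw of integer totals with the target post-discretization mean.
.rdiscnorm <- function(n, target_mean, sigma, lo, hi) {
  mu <- .calibrate_discnorm_mu(target_mean, sigma, lo, hi)
  if (sigma <= 0) return(rep(min(max(round(mu), lo), hi), n))
  x <- round(stats::rnorm(n, mu, sigma))
  as.integer(pmin(pmax(x, lo), hi))
}

# Quantile draw from the calibrated discretized normal given uniforms,
# used to couple instruments through a shared severity factor while
# preserving each marginal pmf (and hence the calibrated mean) exactly.
.qdiscnorm <- function(u, target_mean, sigma, lo, hi) {
  mu <- .calibrate_discnorm_mu(target_mean, sigma, lo, hi)
  if (sigma <= 0) return(rep(min(max(round(mu), lo), hi), length(u)))
  p <- .discnorm_pmf(mu, sigma, lo, hi)
  support <- lo:hi
  cum <- cumsum(p)
  idx <- pmin(findInterval(u, cum, left.open = TRUE) + 1L, length(support))
  as.integer(support[idx])
}

#' Default per-phenotype calibration targets
#'
#' Per-phenotype means and SDs of the three mental-health totals, age and
#' education, category probabilities for the CTQ subscales, covariate
#' endorsement rates and cognitive-score distributions. Values are the
#' published per-cluster summary statistics of the reference cohort the
#' generator emulates (n = 277; clusters of 76/32/130/39).
#'
#' @return Nested list of calibration targets keyed by variable.
#' @export
default_phenotype_targets <- function() {
  list(
    # Per-phenotype mean/SD of the totals plus the score window each
    # phenotype occupies. Density clustering partitions score space, so the
    # published phenotypes correspond to disjoint score regions; the windows
    # (lo/hi rows C1..C4) encode those regions, leaving the boundary lattice
    # planes empty, while the post-truncation means stay calibrated to the
    # published cluster means.
    score = list(
      BAI  = list(mean = c(7.76, 5.03, 1.15, 0),
                  sd   = c(7.46, 1.91, 1.54, 0),
                  window = rbind(c(0, 63), c(4, 8), c(0, 2), c(0, 0))),
      PHQ9 = list(mean = c(5.09, 2.34, 1.08, 0.05),
                  sd   = c(4.19, 2.22, 1.60, 0.22),
                  window = rbind(c(0, 27), c(0, 4), c(0, 4), c(0, 1))),
      PCLC = list(mean = c(37.14, 20.81, 21.52, 17.1),
                  sd   = c(8.80, 1.67, 3.1, 0.31),
                  window = rbind(c(33, 85), c(19, 23), c(20, 26), c(17, 18)))
    ),
    # CTQ category probabilities per phenotype (rows C1..C4), columns in
    # ctq_levels() order; derived from per-cluster category counts.
    ctq = list(
      PA = rbind(c(55, 10, 11), c(28, 3, 1), c(114, 9, 7), c(33, 4, 2)) /
        c(76, 32, 130, 39),
      SA = rbind(c(44, 11, 21), c(27, 5, 0), c(105, 15, 10), c(32, 2, 5)) /
        c(76, 32, 130, 39)
    ),
    age = list(mean = c(42.92, 49.59, 44.04, 41.74),
               sd   = c(9.54, 8.08, 8.49, 6.86)),
    education = list(mean = c(6.00, 6.47, 6.03, 6.97),
                     sd   = c(3.62, 3.94, 3.71, 3.49)),
    male_prop = c(0.37, 0.41, 0.50, 0.54),
    married_prop = c(0.49, 0.41, 0.68, 0.59),
    viral_detectable_prop = c(0.12, 0.06, 0.05, 0.03),
    flags = list(
      sensory_symptoms   = c(0.50, 0.47, 0.21, 0.05),
      balance_difficulty = c(0.05, 0.06, 0.00, 0.00),
      fit_seizure        = c(0.04, 0.00, 0.01, 0.00),
      smoke              = c(0.13, 0.16, 0.07, 0.08),
      hypertension       = c(0.09, 0.03, 0.05, 0.00),
      diabetes           = c(0.01, 0.00, 0.01, 0.00),
      med_niazid         = c(0.63, 0.75, 0.70, 0.82),
      med_dapsone        = c(0.01, 0.09, 0.04, 0.05),
      med_flagyl         = c(0.05, 0.03, 0.00, 0.00),
      med_antihypertensive = c(0.07, 0.00, 0.02, 0.00)
    ),
    cognition = list(
      avlt_total_learning = list(mean = c(49.13, 47.28, 47.42, 47.10),
                                 sd = c(8.10, 8.10, 8.32, 6.97)),
      avlt_delayed_recall = list(mean = c(10.42, 9.56, 10.02, 9.46),
                                 sd = c(2.46, 2.71, 2.48, 2.26)),
      avlt_recognition    = list(mean = c(14.04, 14.06, 13.63, 12.82),
                                 sd = c(1.25, 1.13, 1.64, 3.17)),
      pegs_dominant       = list(mean = c(83.95, 88.26, 79.60, 77.00),
                                 sd = c(25.87, 25.12, 21.70, 18.64)),
      pegs_nondominant    = list(mean = c(97.84, 105.50, 89.34, 94.32),
                                 sd = c(31.60, 31.57, 23.77, 27.23)),
      color_trails1_time  = list(mean = c(92.59, 99.90, 89.33, 81.57),
                                 sd = c(36.45, 35.07, 29.67, 27.09)),
      color_trails2_time  = list(mean = c(196.33, 197.86, 186.40, 172.19),
                                 sd = c(72.62, 66.97, 67.08, 62.74)),
      symbol_digit        = list(mean = c(19.17, 17.69, 18.83, 19.97),
                                 sd = c(10.60, 9.62, 10.17, 10.59)),
      timed_gait          = list(mean = c(11.46, 11.08, 11.19, 10.70),
                                 sd = c(1.85, 1.28, 1.55, 1.55))
    ),
    near_misses = list(
      color_trails1_near_misses = list(mean = c(0.19, 0.06, 0.13, 0.26),
                                       sd = c(0.40, 0.25, 0.38, 0.72)),
      color_trails2_near_misses = list(mean = c(0.30, 0.48, 0.30, 0.18),
                                       sd = c(0.52, 0.89, 0.64, 0.69))
    ),
    # CES-D positive-affect items (happy, enjoyed life, hopeful, felt as good
    # as others), 0-3 ordinal. Not published per cluster; defaults plant the
    # lower positive affect of the PTSD phenotype reported at item level.
    cesd_pa = list(mean = c(1.3, 2.0, 2.1, 2.4), sd = c(0.8, 0.8, 0.8, 0.7)),
    # Functional status and ART exposure; modest phenotype gradient in
    # functional status, shared ART-duration baseline.
    karnofsky = list(mean = c(88, 90, 92, 93), sd = c(8, 8, 8, 8)),
    art_duration_months = list(mean = c(84, 84, 84, 84), sd = c(36, 36, 36, 36)),
    # Within-phenotype coupling of the three totals through a shared latent
    # severity factor (Gaussian copula); marginals stay exactly calibrated.
    # Default 0: totals independent given the phenotype.
    score_factor_cor = 0
  )
}

#' BAI somatic/physical item subset
#'
#' Item indices of the somatic/physical anxiety symptoms (numbness, feeling
#' hot, wobbliness, dizziness, pounding heart, unsteadiness, indigestion,
#' faintness, flushing, sweats, ...), used to plant the somatic-heavy
#' anxiety-phenotype signature in the generator and to contrast somatic vs
#' affective item profiles.
#'
#' @return Integer vector of BAI item indices.
#' @export
bai_somatic_items <- function() {
  c(1L, 2L, 3L, 6L, 7L, 8L, 11L, 12L, 13L, 15L, 18L, 19L, 20L, 21L)
}

# Default item-allocation weight profiles per phenotype: plant the reported
# item-level signatures (anhedonia-heavy depression in the PTSD phenotype,
# vegetative/somatic loading in the anxiety phenotype, flat cognitive PTSD
# items) while keeping other items exchangeable.
default_item_weights <- function() {
  w <- list()
  for (ph in phenotype_ids()) {
    w[[ph]] <- list(
      PHQ9 = rep(1, 9), BAI = rep(1, 21), PCLC = rep(1, 17),
      CTQ_PA = rep(1, 5), CTQ_SA = rep(1, 5)
    )
  }
  w$C1$PHQ9[1] <- 3                       # anhedonia
  w$C2$PHQ9[c(3, 4, 5)] <- 3              # sleep, fatigue, appetite
  w$C2$BAI[bai_somatic_items()] <- 3      # physical anxiety symptoms
  w$C1$PCLC[c(8, 9, 10)] <- 0.5           # cognitive/avoidance items endorsed less
  w
}

#' Build a synthetic-cohort configuration
#'
#' @param n Cohort size (default 277).
#' @param prevalences Probability vector over the four phenotypes
#'   (default 0.274, 0.116, 0.469, 0.141).
#' @param targets Calibration targets, see [default_phenotype_targets()].
#' @param item_weights Per-phenotype item-allocation weights, see
#'   [default_item_weights()].
#' @param exact_counts If `TRUE` phenotype counts are fixed at
#'   `round(n * prevalences)` instead of multinomial draws.
#' @param seed Integer seed recorded in the config (used by
#'   [generate_cohort()] unless overridden).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n = 277L,
                          prevalences = c(0.274, 0.116, 0.469, 0.141),
                          targets = default_phenotype_targets(),
                          item_weights = default_item_weights(),
                          exact_counts = FALSE,
                          seed = 1L) {
  stopifnot(length(prevalences) == 4, all(prevalences >= 0))
  if (abs(sum(prevalences) - 1) > 1e-6) {
    stop("prevalences must sum to 1", call. = FALSE)
  }
  if (n < 4) stop("n must be at least the number of phenotypes", call. = FALSE)
  for (ins in names(targets$score)) {
    if (any(targets$score[[ins]]$sd < 0)) stop("SDs must be >= 0", call. = FALSE)
  }
  structure(list(n = as.integer(n), prevalences = prevalences,
                 targets = targets, item_weights = item_weights,
                 exact_counts = isTRUE(exact_counts), seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> n=%d, prevalences=%s, seed=%d%s\n", x$n,
              paste(format(x$prevalences), collapse = "/"), x$seed,
              if (x$exact_counts) ", exact counts" else ""))
  invisible(x)
}

#' Distribute a total score across instrument items
#'
#' Allocates `total` over the items of an instrument so that the items sum
#' exactly to the total, every item stays within its range, and the expected
#' item loadings (above the item minimum) are proportional to
#' `profile_weights`. Units of score above the forced minimum are assigned
#' one at a time to items drawn with probability proportional to their weight
#' among items that still have capacity.
#'
#' @param total Integer total to distribute.
#' @param spec An [instrument_spec()].
#' @param profile_weights Nonnegative weights, one per item.
#' @return Integer vector of item responses summing to `total`.
#' @export
allocate_items <- function(total, spec, profile_weights = rep(1, spec$n_items)) {
  stopifnot(inherits(spec, "instrument_spec"),
            length(profile_weights) == spec$n_items,
            all(profile_weights >= 0))
  if (total < spec$total_min || total > spec$total_max) {
    stop(sprintf("total %d unachievable for %s (range [%d, %d])",
                 total, spec$name, spec$total_min, spec$total_max), call. = FALSE)
  }
  items <- rep(spec$item_min, spec$n_items)
  excess <- total - spec$total_min
  cap <- spec$item_max - spec$item_min
  if (all(profile_weights == 0)) profile_weights <- rep(1, spec$n_items)
  while (excess > 0L) {
    open <- which(items - spec$item_min < cap & profile_weights > 0)
    if (length(open) == 0L) open <- which(items - spec$item_min < cap)
    k <- if (length(open) == 1L) open else {
      w <- profile_weights[open]
      if (all(w == 0)) w <- rep(1, length(open))
      open[sample.int(length(open), 1L, prob = w)]
    }
    items[k] <- items[k] + 1L
    excess <- excess - 1L
  }
  as.integer(items)
}

.rbinary <- function(n, p) stats::runif(n) < p

#' Generate a seeded synthetic cohort
#'
#' Draws latent phenotype labels, instrument totals from truncated discretized
#' normals calibrated so the post-truncation means equal the per-phenotype
#' targets, item vectors summing exactly to the totals with phenotype-specific
#' item signatures, CTQ subscale totals consistent with the target category
#' probabilities, and the demographic, HIV-index, medical, medication,
#' functional and cognitive covariates.
#'
#' The latent phenotype label (`latent_phenotype`) is ground truth for
#' evaluation only; no analysis stage consumes it.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return Data frame of participant records, one row per participant, with
#'   attributes `seed` and `planted_effects`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n
  tg <- config$targets
  ph_ids <- phenotype_ids()

  if (config$exact_counts) {
    counts <- round(n * config$prevalences)
    counts[4] <- n - sum(counts[1:3])
    phen <- rep(ph_ids, times = counts)
    phen <- phen[sample.int(n)]
  } else {
    phen <- ph_ids[sample.int(4, n, replace = TRUE, prob = config$prevalences)]
  }
  pi <- match(phen, ph_ids)

  cohort <- data.frame(id = sprintf("P%04d", seq_len(n)),
                       latent_phenotype = phen, stringsAsFactors = FALSE)

  # instrument totals and item vectors: per participant a shared severity
  # factor couples the three totals; each total is the quantile of the
  # phenotype's calibrated windowed discretized normal
  rho <- tg$score_factor_cor
  if (is.null(rho)) rho <- 0
  z_common <- stats::rnorm(n)
  item_cols <- list()
  for (ins in c("PHQ9", "BAI", "PCLC")) {
    spec <- instrument_spec(ins)
    win <- tg$score[[ins]]$window
    if (is.null(win)) {
      win <- matrix(c(spec$total_min, spec$total_max), 4, 2, byrow = TRUE)
    }
    z_ins <- sqrt(rho) * z_common + sqrt(1 - rho) * stats::rnorm(n)
    u <- stats::pnorm(z_ins)
    tot <- integer(n)
    for (k in seq_along(ph_ids)) {
      idx <- which(pi == k)
      if (length(idx) == 0) next
      lo <- max(win[k, 1], spec$total_min)
      hi <- min(win[k, 2], spec$total_max)
      tot[idx] <- .qdiscnorm(u[idx], tg$score[[ins]]$mean[k],
                             tg$score[[ins]]$sd[k], lo, hi)
    }
    prefix <- tolower(ins)
    mat <- matrix(0L, n, spec$n_items)
    for (i in seq_len(n)) {
      mat[i, ] <- allocate_items(tot[i], spec,
                                 config$item_weights[[phen[i]]][[ins]])
    }
    colnames(mat) <- paste0(prefix, "_item", seq_len(spec$n_items))
    item_cols[[ins]] <- mat
  }

  # CTQ subscales: category drawn from per-phenotype probabilities, then a
  # total drawn within the category's score band (geometric-like decay so
  # low totals dominate within a band), then items.
  ctq_cuts <- default_ctq_cutoffs()
  for (sub in c("PA", "SA")) {
    spec <- instrument_spec(paste0("CTQ_", sub))
    cuts <- ctq_cuts[[sub]]
    bands <- list(c(5L, cuts[["low_moderate"]] - 1L),
                  c(cuts[["low_moderate"]], cuts[["moderate_extreme"]] - 1L),
                  c(cuts[["moderate_extreme"]], 25L))
    tot <- integer(n)
    for (k in seq_along(ph_ids)) {
      idx <- which(pi == k)
      if (length(idx) == 0) next
      cat_idx <- sample.int(3, length(idx), replace = TRUE, prob = tg$ctq[[sub]][k, ])
      for (b in 1:3) {
        sel <- idx[cat_idx == b]
        if (length(sel) == 0) next
        lo <- bands[[b]][1]; hi <- bands[[b]][2]
        support <- lo:hi
        w <- 0.5^(seq_along(support) - 1)
        tot[sel] <- support[sample.int(length(support), length(sel),
                                       replace = TRUE, prob = w)]
      }
    }
    prefix <- paste0("ctq_", tolower(sub))
    mat <- matrix(0L, n, spec$n_items)
    ins <- paste0("CTQ_", sub)
    for (i in seq_len(n)) {
      mat[i, ] <- allocate_items(tot[i], spec,
                                 config$item_weights[[phen[i]]][[ins]])
    }
    colnames(mat) <- paste0(prefix, "_item", seq_len(spec$n_items))
    item_cols[[ins]] <- mat
  }
  for (mat in item_cols) cohort <- cbind(cohort, as.data.frame(mat))

  # CES-D positive-affect items, 0-3 ordinal, per-phenotype means
  for (j in 1:4) {
    x <- integer(n)
    for (k in seq_along(ph_ids)) {
      idx <- which(pi == k)
      if (length(idx) == 0) next
      x[idx] <- .rdiscnorm(length(idx), tg$cesd_pa$mean[k], tg$cesd_pa$sd[k], 0L, 3L)
    }
    cohort[[paste0("cesd_pa_item", j)]] <- x
  }

  # demographics and HIV indices
  cohort$age <- round(pmax(18, stats::rnorm(n, tg$age$mean[pi], tg$age$sd[pi])), 1)
  cohort$sex <- ifelse(.rbinary(n, tg$male_prop[pi]), "male", "female")
  cohort$education_years <- round(pmax(0, stats::rnorm(n, tg$education$mean[pi],
                                                       tg$education$sd[pi])))
  cohort$marital_status <- ifelse(.rbinary(n, tg$married_prop[pi]),
                                  "married", "not_married")
  cohort$viral_load_detectable <- .rbinary(n, tg$viral_detectable_prop[pi])
  cohort$art_duration_months <- round(pmax(6, stats::rnorm(
    n, tg$art_duration_months$mean[pi], tg$art_duration_months$sd[pi])))
  cohort$karnofsky <- pmin(100, pmax(50, 10 * round(stats::rnorm(
    n, tg$karnofsky$mean[pi], tg$karnofsky$sd[pi]) / 10)))

  # medical history, symptoms, medication flags
  for (fl in names(tg$flags)) {
    cohort[[fl]] <- as.integer(.rbinary(n, tg$flags[[fl]][pi]))
  }

  # cognitive and motor raw scores
  for (cg in names(tg$cognition)) {
    cohort[[cg]] <- round(pmax(0, stats::rnorm(n, tg$cognition[[cg]]$mean[pi],
                                               tg$cognition[[cg]]$sd[pi])), 2)
  }
  for (nm in names(tg$near_misses)) {
    cohort[[nm]] <- pmax(0L, round(stats::rnorm(n, tg$near_misses[[nm]]$mean[pi],
                                                tg$near_misses[[nm]]$sd[pi])))
  }

  attr(cohort, "seed") <- as.integer(seed)
  attr(cohort, "planted_effects") <- list()
  cohort
}

#' Plant known-truth feature-phenotype associations
#'
#' Overwrites (binary flags) or shifts (numeric columns) features so that
#' requested marginal associations with the latent phenotype hold in
#' expectation. Used to create known-truth discriminative features for
#' classifier-recovery experiments; every planted effect is recorded in the
#' `planted_effects` attribute of the returned cohort.
#'
#' @param cohort A cohort from [generate_cohort()] (must carry
#'   `latent_phenotype`).
#' @param effects Named list: each element is either
#'   `list(rate = c(p1, p2, p3, p4))` for a binary feature (per-phenotype
#'   Bernoulli rates) or `list(delta = c(d1, d2, d3, d4))` for a numeric
#'   feature (per-phenotype additive mean shifts). The element name is the
#'   feature column.
#' @param seed Optional seed for the redraw (default: leave the RNG stream
#'   as-is).
#' @return The cohort with modified features and updated `planted_effects`.
#' @export
plant_classifier_signal <- function(cohort, effects, seed = NULL) {
  stopifnot(is.list(effects), !is.null(cohort$latent_phenotype))
  if (!is.null(seed)) set.seed(seed)
  pi <- match(cohort$latent_phenotype, phenotype_ids())
  planted <- attr(cohort, "planted_effects")
  if (is.null(planted)) planted <- list()
  for (feat in names(effects)) {
    if (!feat %in% names(cohort)) {
      stop(sprintf("unknown feature '%s'", feat), call. = FALSE)
    }
    eff <- effects[[feat]]
    if (!is.null(eff$rate)) {
      stopifnot(length(eff$rate) == 4, all(eff$rate >= 0 & eff$rate <= 1))
      cohort[[feat]] <- as.integer(.rbinary(nrow(cohort), eff$rate[pi]))
    } else if (!is.null(eff$delta)) {
      stopifnot(length(eff$delta) == 4)
      cohort[[feat]] <- cohort[[feat]] + eff$delta[pi]
    } else {
      stop(sprintf("effect for '%s' must give 'rate' or 'delta'", feat),
           call. = FALSE)
    }
    planted[[feat]] <- eff
  }
  attr(cohort, "planted_effects") <- planted
  cohort
}
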