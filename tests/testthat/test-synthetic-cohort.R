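test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(cohort_config(seed = 7))
  b <- generate_cohort(cohort_config(seed = 7))
  expect_identical(a, b)
  c <- generate_cohort(cohort_config(seed = 8))
  expect_false(identical(a, c))
})

test_that("phenotype counts follow the configured prevalences", {
  co <- generate_cohort(cohort_config(seed = 3))
  counts <- table(factor(co$latent_phenotype, phenotype_ids()))
  expected <- 277 * c(0.274, 0.116, 0.469, 0.141)
  # multinomial draw: within 4 SD of expectation
  sds <- sqrt(expected * (1 - expected / 277))
  expect_true(all(abs(counts - expected) < 4 * sds))
  ex <- generate_cohort(cohort_config(seed = 3, exact_counts = TRUE))
  expect_equal(as.integer(table(factor(ex$latent_phenotype, phenotype_ids()))),
               c(76, 32, 130, 39), tolerance = 0)
})

test_that("calibrated discretized-normal sampler reproduces target means", {
  tg <- default_phenotype_targets()
  # exact pmf means equal the published per-cluster means by construction
  for (ins in c("BAI", "PHQ9", "PCLC")) {
    spec <- instrument_spec(ins)
    for (k in 1:4) {
      lo <- max(tg$score[[ins]]$window[k, 1], spec$total_min)
      hi <- min(tg$score[[ins]]$window[k, 2], spec$total_max)
      m <- tg$score[[ins]]$mean[k]; s <- tg$score[[ins]]$sd[k]
      mu <- mhpheno:::.calibrate_discnorm_mu(m, s, lo, hi)
      pmf <- mhpheno:::.discnorm_pmf(mu, s, lo, hi)
      expect_equal(sum((lo:hi) * pmf), m, tolerance = 1e-6)
    }
  }
  # Monte-Carlo: simulated PCL-C means at n = 10,000 per phenotype within
  # 2 SE of the published cluster means
  set.seed(99)
  for (k in 1:4) {
    m <- tg$score$PCLC$mean[k]; s <- tg$score$PCLC$sd[k]
    lo <- tg$score$PCLC$window[k, 1]; hi <- tg$score$PCLC$window[k, 2]
    draws <- mhpheno:::.rdiscnorm(10000, m, s, lo, hi)
    se <- max(sd(draws) / sqrt(10000), 1e-3)
    expect_lt(abs(mean(draws) - m), 2 * se + 0.02)
  }
  expect_error(mhpheno:::.calibrate_discnorm_mu(30, 2, 0, 27), "infeasible")
})

test_that("item allocation conserves totals and respects forced extremes", {
  spec <- instrument_spec("PCLC")
  expect_equal(allocate_items(17, spec), rep(1L, 17))
  expect_equal(allocate_items(85, spec), rep(5L, 17))
  expect_error(allocate_items(16, spec), "unachievable")
  set.seed(11)
  for (tot in sample(17:85, 20)) {
    items <- allocate_items(tot, spec)
    expect_equal(sum(items), tot)
    expect_true(all(items >= 1 & items <= 5))
  }
})

test_that("item allocation loads items in proportion to profile weights", {
  spec <- instrument_spec("PHQ9")
  set.seed(21)
  uni <- colMeans(t(replicate(800, allocate_items(9, spec))))
  expect_lt(max(abs(uni - 1)), 0.15)  # uniform weights: symmetric loadings
  w <- c(4, rep(1, 8))
  heavy <- colMeans(t(replicate(800, allocate_items(9, spec, w))))
  expect_gt(heavy[1], 2 * mean(heavy[-1]))
})

test_that("planted signals reach their target rates; unknown features error", {
  cfg <- cohort_config(n = 4000, prevalences = rep(0.25, 4), seed = 13)
  co <- generate_cohort(cfg)
  co <- plant_classifier_signal(co, list(
    sensory_symptoms = list(rate = c(0.5, 0.47, 0.21, 0.05)),
    age = list(delta = c(0, 5, 0, 0))))
  pi <- match(co$latent_phenotype, phenotype_ids())
  rates <- tapply(co$sensory_symptoms, pi, mean)
  for (k in 1:4) {
    p <- c(0.5, 0.47, 0.21, 0.05)[k]
    n_k <- sum(pi == k)
    expect_lt(abs(rates[k] - p), 2.5 * sqrt(p * (1 - p) / n_k) + 0.01)
  }
  expect_true("sensory_symptoms" %in% names(attr(co, "planted_effects")))
  expect_error(plant_classifier_signal(co, list(nope = list(rate = rep(0.5, 4)))),
               "unknown feature")
})

test_that("zero-effect plants leave features independent of phenotype", {
  cfg <- cohort_config(n = 4000, prevalences = rep(0.25, 4), seed = 17)
  co <- generate_cohort(cfg)
  co <- plant_classifier_signal(co, list(smoke = list(rate = rep(0.3, 4))))
  tb <- table(co$latent_phenotype, co$smoke)
  p <- suppressWarnings(chisq.test(tb, correct = FALSE))$p.value
  expect_gt(p, 0.001)
})

test_that("pooled total-score means converge to the prevalence-weighted targets", {
  tg <- default_phenotype_targets()
  cfg <- cohort_config(n = 8000, seed = 19)
  sc <- score_cohort(generate_cohort(cfg))
  prev <- c(0.274, 0.116, 0.469, 0.141)
  for (ins in c("BAI", "PHQ9", "PCLC")) {
    col <- paste0(switch(ins, BAI = "bai", PHQ9 = "phq9", PCLC = "pclc"),
                  "_total")
    target <- sum(prev * tg$score[[ins]]$mean)
    expect_lt(abs(mean(sc[[col]]) - target), 3.5 * sd(sc[[col]]) / sqrt(8000))
  }
})

test_that("latent truth labels are absent from every analysis artifact", {
  sc <- test_cohort()
  sol <- phenotype_clustering(sc, embedding_config(seed = 1))
  comp <- compare_to_referent(sc, sol$labels, referent = max(sol$labels))
  expect_false(any(grepl("latent", comp$variable)))
  expect_false("latent_phenotype" %in% default_classifier_features())
})
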