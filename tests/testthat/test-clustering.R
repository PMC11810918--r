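test_that("silhouette matches a hand-computed toy value and the brute-force oracle", {
  # two pairs: within-pair distance 1, between-pair distance ~10
  x <- matrix(c(0, 0, 1, 0, 10, 0, 11, 0), ncol = 2, byrow = TRUE)
  labels <- c(1, 1, 2, 2)
  got <- evaluate_silhouette(x, labels)
  # closed form: a = 1, b = mean(10, 11) = 10.5 for each point (symmetric)
  expect_equal(got, mean(c((10.5 - 1) / 10.5, (9.5 - 1) / 9.5)),
               tolerance = 1e-10)
  expect_equal(got, brute_silhouette(x, labels), tolerance = 1e-10)
  set.seed(14)
  y <- matrix(rnorm(60), 30, 2)
  lab <- rep(1:3, each = 10)
  expect_equal(evaluate_silhouette(y, lab), brute_silhouette(y, lab),
               tolerance = 1e-10)
})

test_that("co-located duplicated clusters give non-positive silhouette", {
  set.seed(15)
  x <- matrix(rnorm(40), 20, 2)
  x2 <- rbind(x, x)
  labels <- rep(1:2, each = 20)  # identical point sets labeled differently
  expect_lte(evaluate_silhouette(x2, labels), 0)
})

test_that("silhouette requires at least two non-noise clusters", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(evaluate_silhouette(x, rep(1, 10)), "fewer than 2")
  expect_error(evaluate_silhouette(x, c(rep(1, 9), 0)), "fewer than 2")
})

test_that("phenotype labeling follows the deterministic rubric", {
  summaries <- data.frame(
    cluster = 1:4,
    bai_mean = c(7.76, 5.03, 1.15, 0),
    phq9_mean = c(5.09, 2.34, 1.08, 0.05),
    pclc_mean = c(37.14, 20.81, 21.52, 17.1))
  ph <- label_phenotypes(summaries)
  expect_equal(unname(ph), c("PTSD", "anxiety", "mixed_anxiety_depression",
                             "minimal_symptom"))
  # all-minima cluster is forced to minimal_symptom
  s2 <- data.frame(cluster = 1:4,
                   bai_mean = c(10, 5, 3, 0), phq9_mean = c(9, 4, 2, 0),
                   pclc_mean = c(40, 25, 22, 17))
  expect_equal(unname(label_phenotypes(s2)[4]), "minimal_symptom")
  # sub-threshold pair split by BAI mean
  expect_equal(unname(label_phenotypes(summaries)[2]), "anxiety")
  expect_equal(unname(label_phenotypes(summaries)[3]),
               "mixed_anxiety_depression")
  # cluster counts other than four: never dropped, unlabeled allowed
  s3 <- summaries[1:3, ]
  ph3 <- label_phenotypes(s3)
  expect_equal(length(ph3), 3)
  expect_true(all(ph3 %in% phenotype_names()))
  s5 <- rbind(summaries, data.frame(cluster = 5, bai_mean = 2, phq9_mean = 2,
                                    pclc_mean = 24))
  ph5 <- label_phenotypes(s5)
  expect_equal(length(ph5), 5)
  expect_true("unlabeled" %in% ph5)
})

test_that("end-to-end clustering recovers the planted phenotype structure", {
  sc <- test_cohort()
  sol <- phenotype_clustering(sc, embedding_config(seed = 101))
  k <- sum(names(sol$cluster_sizes) != "noise")
  expect_gte(k, 3)
  expect_lte(k, 5)
  mask <- sol$labels != 0
  ari <- mclust::adjustedRandIndex(sc$latent_phenotype[mask],
                                   sol$labels[mask])
  expect_gt(ari, 0.5)  # smoke check; the 20-seed recovery bound lives in
                       # the acceptance suite
  expect_gt(sol$silhouette, 0.4)
  expect_equal(sum(sol$cluster_sizes), nrow(sc))
  # PTSD and minimal phenotypes present
  expect_true(all(c("PTSD", "minimal_symptom") %in% sol$phenotypes))
})

test_that("noise reassignment empties the noise set and conserves weighted means", {
  sc <- test_cohort()
  sol <- phenotype_clustering(sc, embedding_config(seed = 101),
                              reassign_noise = TRUE)
  expect_false("noise" %in% names(sol$cluster_sizes))
  # prevalence-weighted per-cluster means reproduce the cohort mean exactly
  w <- sol$summaries$n / sum(sol$summaries$n)
  expect_equal(sum(w * sol$summaries$pclc_mean), mean(sc$pclc_total),
               tolerance = 1e-10)
  expect_equal(sum(w * sol$summaries$bai_mean), mean(sc$bai_total),
               tolerance = 1e-10)
})
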