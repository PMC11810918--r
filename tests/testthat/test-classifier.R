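test_that("F1 equals the harmonic mean of precision and recall", {
  # precision 0.5, recall 1 -> 2/3
  truth <- c(1, 1, 0, 0)
  pred <- c(1, 1, 1, 1)
  expect_equal(f1_score(truth, pred, 1), 2 / 3)
  expect_equal(f1_score(truth, truth, 1), 1)
  expect_equal(f1_score(truth, 1 - truth, 1), 0)
  set.seed(51)
  for (i in 1:100) {
    t_i <- rbinom(30, 1, 0.5)
    p_i <- rbinom(30, 1, 0.5)
    expect_equal(f1_score(t_i, p_i, 1), brute_f1(t_i, p_i, 1))
  }
})

test_that("boosted probabilities live in [0, 1] and separate separable classes", {
  set.seed(52)
  n <- 200
  x <- data.frame(f = c(rnorm(n / 2, -2), rnorm(n / 2, 2)))
  y <- rep(c("a", "b"), each = n / 2)
  model <- fit_boost(x, y, positive = "b", seed = 1)
  p <- predict_prob(model, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(f1_score(y, ifelse(p > 0.5, "b", "a"), "b"), 1,
               tolerance = 0.05)
})

test_that("repeated CV returns folds x repeats trials and is seed-reproducible", {
  set.seed(53)
  fx <- simulate_selection_fixture(n = 150, n_noise = 3, seed = 3)
  r1 <- cv_f1(fx$features, fx$labels, folds = 5, repeats = 5, seed = 9)
  r2 <- cv_f1(fx$features, fx$labels, folds = 5, repeats = 5, seed = 9)
  expect_identical(r1, r2)
  expect_length(r1$per_trial, 25)
  expect_equal(r1$mean, mean(r1$per_trial))
  expect_equal(r1$sd, sd(r1$per_trial))
  r3 <- cv_f1(fx$features, fx$labels, folds = 5, repeats = 5, seed = 10)
  expect_false(identical(r1$per_trial, r3$per_trial))
  # too few positives to stratify
  y_rare <- factor(c(rep("a", 147), rep("b", 3)))
  expect_error(cv_f1(fx$features, y_rare, folds = 5), "stratify")
})

test_that("a perfectly separating feature saturates selection immediately", {
  set.seed(54)
  n <- 200
  y <- factor(rep(c("ctrl", "case"), each = n / 2), c("ctrl", "case"))
  df <- data.frame(perfect = as.numeric(y == "case") + rnorm(n, sd = 0.01),
                   j1 = rnorm(n), j2 = rnorm(n))
  sel <- select_features(df, y, seed = 4, positive = "case")
  expect_equal(sel$features[1], "perfect")
  expect_lte(length(sel$features), 2)
  expect_gt(sel$mean, 0.95)
})

test_that("selection trace is reproducible bit-for-bit under a fixed seed", {
  fx <- simulate_selection_fixture(n = 200, n_noise = 10, seed = 5)
  s1 <- select_features(fx$features, fx$labels, seed = 6)
  s2 <- select_features(fx$features, fx$labels, seed = 6)
  expect_identical(s1, s2)
  expect_true(all(s1$trace$mean_f1 >= 0 & s1$trace$mean_f1 <= 1))
  last <- s1$trace$decision[nrow(s1$trace)]
  expect_true(last %in% c("stopped", "kept_exhausted"))
})

test_that("partial dependence is monotone for a planted monotone risk factor", {
  set.seed(55)
  n <- 400
  x <- data.frame(risk = rnorm(n), other = rnorm(n))
  y <- factor(ifelse(rbinom(n, 1, plogis(2 * x$risk)) == 1, "case", "ctrl"),
              c("ctrl", "case"))
  model <- fit_boost(x, y, positive = "case", seed = 7)
  pdp <- partial_dependence(model, x, "risk")
  expect_true(all(pdp$mean_probability >= 0 & pdp$mean_probability <= 1))
  expect_gt(cor(pdp$value, pdp$mean_probability, method = "spearman"), 0.9)
  expect_error(partial_dependence(model, x, "absent"), "unknown feature")
})

test_that("interaction surface peaks in the joint-high corner for a planted synergy", {
  fx <- simulate_synergy_fixture(n = 400, strength = 3, seed = 8)
  inter <- build_interactions(fx$features[, fx$synergy_pair], "two_way")
  model <- fit_boost(inter, fx$labels, positive = "case", seed = 8)
  hm <- interaction_heatmap(model, inter, fx$synergy_pair, grid_size = 5)
  expect_true(all(hm >= 0 & hm <= 1))
  corner_mean <- mean(c(hm[5, 5], hm[1, 1]))   # same-direction corners
  anti_mean <- mean(c(hm[1, 5], hm[5, 1]))     # opposite-direction corners
  expect_gt(corner_mean, anti_mean)
  expect_error(interaction_heatmap(model, inter, c("fa", "absent")),
               "unknown feature")
})

test_that("interaction features match or beat the base model on synergy data", {
  fx <- simulate_synergy_fixture(n = 240, strength = 2.5, seed = 9)
  base <- cv_f1(fx$features, fx$labels, seed = 9)
  with_int <- cv_f1(build_interactions(fx$features, "two_way"), fx$labels,
                    seed = 9)
  expect_gte(with_int$mean, base$mean - base$sd)
})
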