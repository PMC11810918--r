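test_that("pairwise correlation has unit diagonal, symmetry, and exact sign cases", {
  set.seed(41)
  x <- rnorm(200)
  m <- data.frame(a = x, b = -x, c = rnorm(200))
  r <- pairwise_correlation(m)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r["a", "b"], -1, tolerance = 1e-12)
  expect_equal(r, t(r))
  big <- as.data.frame(matrix(rnorm(3 * 10000), ncol = 3))
  rb <- pairwise_correlation(big)
  expect_lt(max(abs(rb[upper.tri(rb)])), 0.05)
})

test_that("zero-variance columns are flagged, not silently dropped", {
  m <- data.frame(a = rnorm(50), z = rep(2, 50))
  expect_warning(r <- pairwise_correlation(m), "zero-variance")
  expect_equal(attr(r, "zero_variance"), "z")
})

test_that("deduplication keeps the highest-MIC member of each correlated group", {
  set.seed(42)
  n <- 300
  y <- factor(rbinom(n, 1, 0.5))
  sig <- rnorm(n) + 2 * (y == 1)
  copy <- sig                               # exact duplicate
  noisy <- sig + rnorm(n, sd = 0.3)         # r > 0.9, weaker MIC vs target
  indep <- rnorm(n)
  fm <- feature_matrix(data.frame(sig = sig, copy = copy, noisy = noisy,
                                  indep = indep))
  out <- dedupe_features(fm, target = y, r_threshold = 0.65)
  expect_equal(sum(c("sig", "copy") %in% names(out)), 1)  # one duplicate kept
  expect_false("noisy" %in% names(out))
  expect_true("indep" %in% names(out))
  r <- pairwise_correlation(out)
  expect_lt(max(abs(r[upper.tri(r)])), 0.65)
})

test_that("deduplication is the identity when no pair crosses the threshold", {
  set.seed(43)
  fm <- feature_matrix(as.data.frame(matrix(rnorm(5 * 200), ncol = 5)))
  y <- factor(rbinom(200, 1, 0.5))
  out <- dedupe_features(fm, y)
  expect_equal(names(out), names(fm))
  expect_equal(attr(out, "removed"), character(0))
})

test_that("two-way interactions carry provenance and avoid division blowups", {
  set.seed(44)
  df <- data.frame(a = rnorm(100), b = rnorm(100), c = c(0, rnorm(99)))
  fm <- build_interactions(df, "two_way")
  prov <- provenance(fm)
  expect_true("a_x_b" %in% names(fm))
  expect_equal(fm$a_x_b, df$a * df$b)
  expect_equal(prov$a_x_b, list(type = "product", parents = c("a", "b")))
  n_prod <- sum(vapply(prov, function(p) p$type == "product", logical(1)))
  n_quot <- sum(vapply(prov, function(p) p$type == "quotient", logical(1)))
  expect_equal(n_prod, 3)
  expect_gte(n_quot, 3)
  expect_lte(n_quot, 6)
  expect_true(all(vapply(as.data.frame(fm), function(col) all(is.finite(col)),
                         logical(1))))
  expect_identical(names(build_interactions(df, "none")), names(df))
})

test_that("multiplying by an all-ones column reproduces the feature", {
  df <- data.frame(a = rnorm(50), ones = rep(1, 50))
  fm <- build_interactions(df, "two_way")
  expect_equal(fm$a_x_ones, df$a)
})
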