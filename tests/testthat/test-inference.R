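test_that("t-test handles equal groups, symmetry and degenerate variances", {
  r <- t_test_summary(5, 2, 20, 5, 2, 20)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  a <- t_test_summary(6, 2, 15, 5, 3, 25)
  b <- t_test_summary(5, 3, 25, 6, 2, 15)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p, b$p)
  z <- t_test_summary(4, 0, 10, 4, 0, 12)
  expect_equal(z$p, 1)
  expect_warning(zz <- t_test_summary(4, 0, 10, 5, 0, 12), "zero variance")
  expect_equal(zz$p, 0)
})

test_that("t-tests from raw vectors agree with the stats::t.test oracle", {
  set.seed(23)
  for (i in 1:20) {
    x <- rnorm(10 + i, mean = runif(1, -1, 1))
    y <- rnorm(8 + i, sd = runif(1, 0.5, 2))
    mine <- t_test_groups(x, y, "welch")
    ref <- t.test(x, y)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    mine_p <- t_test_groups(x, y, "pooled")
    ref_p <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine_p$p, ref_p$p.value, tolerance = 1e-10)
  }
})

test_that("published age contrast between anxiety and minimal clusters reproduces", {
  ref <- reference_cluster_summary()
  c2 <- ref[ref$cluster == "C2", ]
  c4 <- ref[ref$cluster == "C4", ]
  r <- t_test_summary(c2$age_mean, c2$age_sd, c2$n,
                      c4$age_mean, c4$age_sd, c4$n, "welch")
  expect_lt(r$p, 0.001)
  expect_gt(r$statistic, 0)
})

test_that("chi-square equals the brute-force Pearson oracle on random tables", {
  set.seed(29)
  for (i in 1:200) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    tb <- matrix(rpois(nr * nc, lambda = 8) + 1, nr, nc)
    mine <- suppressWarnings(chi_square_test(tb))
    oracle <- brute_chisq(tb)
    expect_equal(mine$statistic, oracle$stat, tolerance = 1e-10)
    expect_equal(mine$df, oracle$df)
    expect_equal(mine$p, oracle$p, tolerance = 1e-10)
  }
})

test_that("identical category proportions give a null chi-square", {
  tb <- rbind(c(10, 20, 30), c(20, 40, 60))
  r <- chi_square_test(tb)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
})

test_that("published abuse-category contrasts reproduce to printed precision", {
  ref <- reference_cluster_summary()
  c1 <- ref[ref$cluster == "C1", ]
  c4 <- ref[ref$cluster == "C4", ]
  sa <- rbind(unlist(c1[, c("sa_none_minimal", "sa_low_moderate",
                            "sa_moderate_extreme")]),
              unlist(c4[, c("sa_none_minimal", "sa_low_moderate",
                            "sa_moderate_extreme")]))
  r_sa <- suppressWarnings(chi_square_test(sa))
  expect_equal(round(r_sa$p, 2), 0.03)
  expect_equal(r_sa$statistic, 6.768, tolerance = 1e-3)
  expect_equal(r_sa$df, 2)
  pa <- rbind(unlist(c1[, c("pa_none_minimal", "pa_low_moderate",
                            "pa_moderate_extreme")]),
              unlist(c4[, c("pa_none_minimal", "pa_low_moderate",
                            "pa_moderate_extreme")]))
  r_pa <- suppressWarnings(chi_square_test(pa))
  expect_equal(round(r_pa$p, 2), 0.26)
  expect_equal(r_pa$statistic, 2.675, tolerance = 1e-3)
})

test_that("chi-square input handling: zero marginals, empty tables, exact option", {
  w <- testthat::capture_warnings(r <- chi_square_test(rbind(c(5, 0, 5),
                                                             c(7, 0, 3))))
  expect_true(any(grepl("zero-marginal", w)))
  expect_equal(r$df, 1)
  expect_error(chi_square_test(matrix(0, 2, 2)), "empty")
  expect_error(suppressWarnings(chi_square_test(rbind(c(5, 0), c(7, 0)))),
               "at least 2")
  ex <- suppressWarnings(chi_square_test(rbind(c(4, 1), c(2, 6)), exact = TRUE))
  expect_equal(ex$test, "fisher_exact")
  expect_true(ex$p >= 0 && ex$p <= 1)
})

test_that("p-value display follows the report convention", {
  expect_equal(format_p(c(0.0339, 0.263, 0.0004, 0.002)),
               c("0.03", "0.26", "<0.001", "<0.01"))
})

test_that("referent comparisons dispatch by type and name unknown variables", {
  sc <- test_cohort()
  sol <- phenotype_clustering(sc, embedding_config(seed = 101))
  ref_cl <- as.integer(names(which(sol$phenotypes == "minimal_symptom")))[1]
  comp <- compare_to_referent(sc, sol$labels, referent = ref_cl)
  expect_true(all(c("cluster", "variable", "test", "statistic", "df", "p",
                    "p_display") %in% names(comp)))
  expect_true(all(comp$p >= 0 & comp$p <= 1))
  expect_equal(unique(comp$test[comp$variable == "age"]), "welch_t")
  expect_true(all(comp$test[comp$variable == "ctq_sa_cat"] ==
                    "pearson_chi_square"))
  k <- sum(names(sol$cluster_sizes) != "noise")
  expect_equal(nrow(comp), (k - 1) * 6)
  expect_error(compare_to_referent(sc, sol$labels, variables = "nonexistent"),
               "unknown variable")
})

test_that("planted abuse excess drives the sexual-abuse contrast monotonically", {
  # stronger planted C1 SA excess => smaller p for C1 vs C4
  p_for <- function(p_extreme) {
    tg <- default_phenotype_targets()
    tg$ctq$SA[1, ] <- c(1 - p_extreme - 0.1, 0.1, p_extreme)
    co <- generate_cohort(cohort_config(n = 1200, targets = tg, seed = 31))
    sc <- score_cohort(co)
    tb <- rbind(table(sc$ctq_sa_cat[sc$latent_phenotype == "C1"]),
                table(sc$ctq_sa_cat[sc$latent_phenotype == "C4"]))
    suppressWarnings(chi_square_test(tb))$p
  }
  expect_lt(p_for(0.45), p_for(0.18))
})
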