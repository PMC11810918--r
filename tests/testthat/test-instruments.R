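test_that("instrument specs match the published item counts and ranges", {
  expect_equal(instrument_spec("PHQ9")[c("n_items", "item_min", "item_max")],
               list(n_items = 9L, item_min = 0L, item_max = 3L))
  expect_equal(instrument_spec("BAI")[c("n_items", "item_min", "item_max")],
               list(n_items = 21L, item_min = 0L, item_max = 3L))
  expect_equal(instrument_spec("PCLC")[c("n_items", "item_min", "item_max")],
               list(n_items = 17L, item_min = 1L, item_max = 5L))
  for (sub in c("CTQ_PA", "CTQ_SA")) {
    expect_equal(instrument_spec(sub)$n_items, 5L)
    expect_equal(instrument_spec(sub)$total_max, 25L)
  }
})

test_that("scoring sums items and hits the instrument extremes", {
  expect_identical(score_instrument(rep(0, 9), instrument_spec("PHQ9")), 0L)
  expect_identical(score_instrument(rep(5, 17), instrument_spec("PCLC")), 85L)
  expect_identical(score_instrument(rep(1, 17), instrument_spec("PCLC")), 17L)
  set.seed(5)
  for (ins in instrument_names()) {
    spec <- instrument_spec(ins)
    r <- sample(spec$item_min:spec$item_max, spec$n_items, replace = TRUE)
    expect_identical(score_instrument(r, spec), as.integer(sum(r)))
  }
})

test_that("scoring rejects malformed input and names the offending item", {
  spec <- instrument_spec("PHQ9")
  expect_error(score_instrument(rep(0, 8), spec), "9 items")
  expect_error(score_instrument(c(rep(0, 4), 7, rep(0, 4)), spec), "item 5")
  expect_error(score_instrument(rep(0.5, 9), spec), "item 1")
})

test_that("missing items fail closed by default and prorate on request", {
  spec <- instrument_spec("PHQ9")
  r <- c(NA, rep(2, 8))
  expect_identical(score_instrument(r, spec), NA_integer_)
  expect_identical(score_instrument(r, spec, missing = "prorate"), 18L)
  r2 <- c(NA, NA, rep(2, 7))
  expect_identical(score_instrument(r2, spec, missing = "prorate"), NA_integer_)
})

test_that("severity banding is total, monotone, and matches the standard cutoffs", {
  expect_equal(as.character(band_severity(0, "PHQ9")), "minimal")
  expect_equal(as.character(band_severity(27, "PHQ9")), "severe")
  bands <- band_severity(0:27, "PHQ9")
  expect_false(anyNA(bands))
  expect_true(all(diff(as.integer(bands)) >= 0))
  expect_equal(as.character(band_severity(c(4, 5, 9, 10, 14, 15, 19, 20), "PHQ9")),
               c("minimal", "mild", "mild", "moderate", "moderate",
                 "moderately_severe", "moderately_severe", "severe"))
  expect_equal(as.character(band_severity(c(7, 8, 15, 16, 25, 26, 63), "BAI")),
               c("minimal", "mild", "mild", "moderate", "moderate",
                 "severe", "severe"))
  expect_error(band_severity(28, "PHQ9"), "outside")
})

test_that("CTQ categorization is monotone with the documented collapse rule", {
  expect_equal(as.character(categorize_ctq(5, "SA")), "none_minimal")
  expect_equal(as.character(categorize_ctq(25, "SA")), "moderate_extreme")
  for (sub in c("PA", "SA")) {
    cats <- categorize_ctq(5:25, sub)
    expect_true(all(diff(as.integer(cats)) >= 0))
    expect_equal(nlevels(cats), 3)
  }
  expect_equal(as.character(categorize_ctq(c(7, 8, 9, 10), "PA")),
               c("none_minimal", "low_moderate", "low_moderate",
                 "moderate_extreme"))
  expect_equal(as.character(categorize_ctq(c(5, 6, 7, 8), "SA")),
               c("none_minimal", "low_moderate", "low_moderate",
                 "moderate_extreme"))
  expect_error(categorize_ctq(4, "PA"), "outside")
})

test_that("cohort scoring appends totals, bands and flags consistent with items", {
  sc <- test_cohort()
  for (ins in instrument_names()) {
    spec <- instrument_spec(ins)
    prefix <- switch(ins, PHQ9 = "phq9", BAI = "bai", PCLC = "pclc",
                     CTQ_PA = "ctq_pa", CTQ_SA = "ctq_sa")
    items <- as.matrix(sc[, paste0(prefix, "_item", seq_len(spec$n_items))])
    tot <- sc[[paste0(prefix, "_total")]]
    expect_identical(tot, as.integer(rowSums(items)))
    expect_true(all(tot >= spec$total_min & tot <= spec$total_max))
  }
  expect_identical(sc$ptsd_flag, sc$pclc_total >= 33)
  # flag is a pure function of PCL-C totals: equal totals, equal flags
  split_flags <- split(sc$ptsd_flag, sc$pclc_total)
  expect_true(all(vapply(split_flags, function(f) length(unique(f)) == 1,
                         logical(1))))
})
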