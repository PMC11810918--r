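test_that("item profiles aggregate back to the per-cluster total-score means", {
  sc <- test_cohort()
  cl <- sc$latent_phenotype
  prof <- profile_items(sc, cl)
  expect_true(all(prof$endorsement_rate >= 0 & prof$endorsement_rate <= 1))
  for (ph in unique(cl)) {
    for (ins in c("PHQ9", "BAI", "PCLC")) {
      total_col <- paste0(switch(ins, PHQ9 = "phq9", BAI = "bai",
                                 PCLC = "pclc"), "_total")
      got <- sum(prof$mean_response[prof$instrument == ins &
                                      prof$cluster == ph])
      expect_equal(got, mean(sc[[total_col]][cl == ph]), tolerance = 1e-10)
    }
  }
})

test_that("profiles of degenerate clusters behave exactly", {
  co <- data.frame(phq9_item1 = c(0L, 2L), phq9_item2 = c(0L, 3L))
  for (k in 3:9) co[[paste0("phq9_item", k)]] <- c(0L, 1L)
  prof <- profile_items(co, c("solo", "other"), instruments = "PHQ9")
  solo <- prof[prof$cluster == "other", ]
  expect_equal(solo$mean_response,
               as.numeric(co[2, paste0("phq9_item", 1:9)]))
  floor_rows <- prof[prof$cluster == "solo", ]
  expect_true(all(floor_rows$mean_response == 0))
  expect_true(all(floor_rows$endorsement_rate == 0))
})

test_that("empty clusters are omitted with a warning", {
  co <- data.frame(matrix(1L, 4, 9))
  names(co) <- paste0("phq9_item", 1:9)
  cl <- factor(rep("a", 4), levels = c("a", "b"))
  expect_warning(prof <- profile_items(co, cl, instruments = "PHQ9"),
                 "empty cluster")
  expect_false("b" %in% prof$cluster)
})

test_that("somatic-weighted anxiety phenotype shows its planted BAI signature", {
  sc <- test_cohort()
  prof <- profile_items(sc, sc$latent_phenotype, instruments = "BAI")
  c2 <- prof[prof$cluster == "C2", ]
  somatic <- c2$mean_response[c2$item %in% bai_somatic_items()]
  affective <- c2$mean_response[!c2$item %in% bai_somatic_items()]
  expect_gt(mean(somatic), mean(affective))
})

test_that("strip-data export is lossless and row-complete", {
  sc <- test_cohort()
  cl <- sc$latent_phenotype
  strip <- export_strip_data(sc, cl)
  expect_equal(nrow(strip), nrow(sc) * 3)
  # re-aggregation reproduces per-cluster mean/SD summaries
  for (ph in unique(cl)) {
    sub <- strip[strip$cluster == ph & strip$instrument == "PCLC", ]
    expect_equal(mean(sub$total), mean(sc$pclc_total[cl == ph]))
    expect_equal(sd(sub$total), sd(sc$pclc_total[cl == ph]))
  }
  # two-participant cohort gives six rows
  expect_equal(nrow(export_strip_data(sc[1:2, ], cl[1:2])), 6)
  # cluster-level PCL-C ordering implied by the calibration
  m <- tapply(strip$total[strip$instrument == "PCLC"],
              strip$cluster[strip$instrument == "PCLC"], mean)
  expect_true(m[["C1"]] > max(m[["C2"]], m[["C3"]]))
  expect_true(min(m[["C2"]], m[["C3"]]) > m[["C4"]])
})
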