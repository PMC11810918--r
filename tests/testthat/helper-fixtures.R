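# Shared helpers for the test suite. All fixtures are generated in code.

# Two well-separated 2-D Gaussian blobs.
make_blobs <- function(n_per = 200, sep = 20, sd = 1, seed = 1) {
  set.seed(seed)
  rbind(
    cbind(rnorm(n_per, 0, sd), rnorm(n_per, 0, sd)),
    cbind(rnorm(n_per, sep, sd), rnorm(n_per, 0, sd))
  )
}

# Brute-force mean silhouette over non-noise points (independent oracle).
brute_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  d <- as.matrix(dist(x))
  mask <- labels != 0
  idx <- which(mask)
  vals <- vapply(idx, function(i) {
    own <- labels[i]
    same <- setdiff(which(labels == own), i)
    if (length(same) == 0) return(0)
    a <- mean(d[i, same])
    others <- setdiff(unique(labels[mask]), own)
    b <- min(vapply(others, function(cl) mean(d[i, labels == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(vals)
}

# Brute-force Pearson chi-square (independent oracle).
brute_chisq <- function(tb) {
  tb <- as.matrix(tb)
  expected <- outer(rowSums(tb), colSums(tb)) / sum(tb)
  stat <- sum((tb - expected)^2 / expected)
  df <- (nrow(tb) - 1) * (ncol(tb) - 1)
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# Brute-force F1 from an explicit confusion matrix (independent oracle).
brute_f1 <- function(truth, pred, positive) {
  cm <- table(factor(truth == positive, c(FALSE, TRUE)),
              factor(pred == positive, c(FALSE, TRUE)))
  tp <- cm["TRUE", "TRUE"]; fp <- cm["FALSE", "TRUE"]; fn <- cm["TRUE", "FALSE"]
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  if (is.na(prec) || is.na(rec) || prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

# Small default synthetic cohort reused across tests.
test_cohort <- local({
  cache <- NULL
  function(seed = 101) {
    if (is.null(cache)) cache <<- score_cohort(generate_cohort(
      cohort_config(seed = seed)))
    cache
  }
})
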