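# Referent-cluster univariate comparisons: Welch/pooled t-tests for
# continuous variables, Pearson chi-square for categorical.

.test_result <- function(test, statistic, df, p, summary = NULL) {
  structure(list(test = test, statistic = statistic, df = df, p = p,
                 summary = summary), class = "mh_test_result")
}

#' @export
print.mh_test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4f, df = %.2f, p = %s\n", x$test,
              x$statistic, x$df, format_p(x$p)))
  invisible(x)
}

#' Two-sample t-test from summary statistics or raw vectors
#'
#' Two-sided t-test, either Welch (Satterthwaite degrees of freedom, the
#' default) or pooled-variance. Accepts group means/SDs/sizes directly, so
#' published summary tables can be tested without raw data; use
#' [t_test_groups()] for raw vectors.
#'
#' Degenerate variances: both SDs zero with equal means gives p = 1 by
#' convention; both zero with unequal means gives p = 0 with a warning.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @param variant `"welch"` or `"pooled"`.
#' @return An `mh_test_result` with `statistic`, `df`, `p`.
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  summ <- data.frame(group = 1:2, mean = c(mean1, mean2), sd = c(sd1, sd2),
                     n = c(n1, n2))
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) {
      return(.test_result(paste0(variant, "_t"), 0, n1 + n2 - 2, 1, summ))
    }
    warning("both groups have zero variance with unequal means; p = 0")
    return(.test_result(paste0(variant, "_t"), sign(mean1 - mean2) * Inf,
                        n1 + n2 - 2, 0, summ))
  }
  if (variant == "welch") {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- (mean1 - mean2) / se
  .test_result(paste0(variant, "_t"), t, df, 2 * stats::pt(-abs(t), df), summ)
}

#' Two-sample t-test from raw vectors
#'
#' @param x,y Numeric vectors for the two groups (NAs dropped).
#' @param variant `"welch"` or `"pooled"`.
#' @return An `mh_test_result`.
#' @export
t_test_groups <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  t_test_summary(mean(x), stats::sd(x), length(x),
                 mean(y), stats::sd(y), length(y), variant)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic on an r x c table of counts with df = (r-1)(c-1) and an
#' upper-tail p-value; no continuity correction by default. Rows or columns
#' with zero marginals are dropped with a warning before testing; a warning
#' is also emitted when any expected cell count is below 5. An exact
#' (Fisher-style) fallback is available with `exact = TRUE`.
#'
#' @param table Matrix of nonnegative integer counts, at least 2 x 2 after
#'   zero-marginal removal.
#' @param correction Apply the Yates continuity correction (2 x 2 only).
#' @param exact Use `fisher.test` instead of the Pearson statistic.
#' @return An `mh_test_result`; for `exact = TRUE`, `statistic` and `df`
#'   are `NA`.
#' @export
chi_square_test <- function(table, correction = FALSE, exact = FALSE) {
  tb <- as.matrix(table)
  if (length(tb) == 0 || sum(tb) == 0) {
    stop("empty contingency table", call. = FALSE)
  }
  if (any(tb < 0)) stop("counts must be nonnegative", call. = FALSE)
  keep_r <- rowSums(tb) > 0
  keep_c <- colSums(tb) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-marginal rows/columns before testing")
    tb <- tb[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tb) < 2 || ncol(tb) < 2) {
    stop("need at least 2 rows and 2 columns with positive counts",
         call. = FALSE)
  }
  expected <- outer(rowSums(tb), colSums(tb)) / sum(tb)
  if (any(expected < 5)) {
    warning("expected cell count below 5; chi-square approximation may be poor")
  }
  if (exact) {
    p <- stats::fisher.test(tb)$p.value
    return(.test_result("fisher_exact", NA_real_, NA_real_, p, tb))
  }
  res <- suppressWarnings(stats::chisq.test(tb, correct = correction))
  .test_result("pearson_chi_square", unname(res$statistic),
               unname(res$parameter), res$p.value, tb)
}

#' Display-format a p-value
#'
#' Report-table convention: two decimals, `"<0.001"` below that threshold,
#' and `"<0.01"` for values that would otherwise display as 0.00.
#'
#' @param p Numeric p-value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001",
         ifelse(round(p, 2) < 0.005, "<0.01", sprintf("%.2f", round(p, 2))))
}

#' Compare clusters to a referent cluster on selected variables
#'
#' For every non-referent cluster and every variable, runs a two-sided test
#' against the referent cluster: Welch (or pooled) t-test for numeric
#' variables, Pearson chi-square on the cluster x category contingency table
#' for categorical/logical variables. The default variable list covers
#' demographics, viral load and early-life-adversity categories.
#'
#' @param cohort Data frame holding the variables.
#' @param cluster Cluster assignment per row (noise rows, label `0` or
#'   `"noise"`, are excluded).
#' @param variables Character vector of column names to test.
#' @param referent Referent cluster id (default the last cluster id).
#' @param t_variant `"welch"` (default) or `"pooled"`.
#' @param correction,exact Passed to [chi_square_test()].
#' @return Data frame with one row per (cluster, variable): `cluster`,
#'   `variable`, `test`, `statistic`, `df`, `p`, `p_display`.
#' @export
compare_to_referent <- function(cohort, cluster,
                                variables = c("age", "sex", "education_years",
                                              "viral_load_detectable",
                                              "ctq_pa_cat", "ctq_sa_cat"),
                                referent = NULL,
                                t_variant = c("welch", "pooled"),
                                correction = FALSE, exact = FALSE) {
  t_variant <- match.arg(t_variant)
  stopifnot(nrow(cohort) == length(cluster))
  miss <- setdiff(variables, names(cohort))
  if (length(miss) > 0) {
    stop("unknown variable(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  keep <- !(cluster %in% c(0, "0", "noise"))
  cohort <- cohort[keep, , drop = FALSE]
  cluster <- cluster[keep]
  ids <- sort(unique(cluster))
  if (is.null(referent)) referent <- ids[length(ids)]
  if (!referent %in% ids || sum(cluster == referent) == 0) {
    stop("referent cluster is empty or absent", call. = FALSE)
  }
  rows <- list()
  for (cl in ids[ids != referent]) {
    for (v in variables) {
      x <- cohort[[v]]
      if (is.numeric(x) && !is.factor(x)) {
        res <- t_test_groups(x[cluster == cl], x[cluster == referent],
                             variant = t_variant)
      } else {
        xf <- factor(x)
        tb <- rbind(table(xf[cluster == cl]), table(xf[cluster == referent]))
        res <- suppressWarnings(chi_square_test(tb, correction = correction,
                                                exact = exact))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, variable = v, test = res$test,
        statistic = res$statistic, df = res$df, p = res$p,
        p_display = format_p(res$p), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
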