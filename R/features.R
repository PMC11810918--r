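# Feature-matrix construction: provenance-tracked columns, Pearson
# redundancy detection, MIC-based deduplication, two-way interaction
# features (products and quotients).

#' Build a provenance-tracked feature matrix
#'
#' @param x Data frame or matrix of numeric (or encodable) columns.
#' @param provenance Optional named list of per-column provenance records;
#'   defaults to `list(type = "base")` for every column.
#' @return Object of class `feature_matrix`: a data frame with a
#'   `provenance` attribute.
#' @export
feature_matrix <- function(x, provenance = NULL) {
  df <- as.data.frame(x)
  if (anyDuplicated(names(df))) stop("column names must be unique", call. = FALSE)
  if (is.null(provenance)) {
    provenance <- stats::setNames(
      rep(list(list(type = "base")), ncol(df)), names(df))
  }
  stopifnot(all(names(df) %in% names(provenance)))
  structure(df, provenance = provenance[names(df)], class = c("feature_matrix",
                                                              "data.frame"))
}

#' Column provenance of a feature matrix
#' @param x A [feature_matrix()].
#' @return Named list of provenance records (`type` is `"base"`, `"product"`
#'   or `"quotient"`; interaction records carry `parents`).
#' @export
provenance <- function(x) attr(x, "provenance")

.fm_subset <- function(x, cols) {
  feature_matrix(as.data.frame(x)[, cols, drop = FALSE],
                 provenance(x)[cols])
}

#' Drop zero-variance columns
#'
#' @param x A [feature_matrix()] (or data frame).
#' @return Feature matrix without constant columns; dropped names in
#'   attribute `dropped`.
#' @export
drop_zero_variance <- function(x) {
  fm <- if (inherits(x, "feature_matrix")) x else feature_matrix(x)
  sds <- vapply(as.data.frame(fm), function(col) stats::sd(as.numeric(col)),
                numeric(1))
  keep <- names(fm)[!is.na(sds) & sds > 0]
  out <- .fm_subset(fm, keep)
  attr(out, "dropped") <- setdiff(names(fm), keep)
  out
}

#' Pairwise Pearson correlation of features
#'
#' @param x Feature matrix or data frame of numeric columns.
#' @return Symmetric correlation matrix with unit diagonal. Zero-variance
#'   columns give `NA` rows/columns and are listed in the `zero_variance`
#'   attribute (with a warning).
#' @export
pairwise_correlation <- function(x) {
  m <- as.matrix(as.data.frame(x))
  storage.mode(m) <- "double"
  if (ncol(m) < 2) stop("need at least two columns", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  flagged <- colnames(m)[sds == 0]
  if (length(flagged) > 0) {
    warning("zero-variance column(s): ", paste(flagged, collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(m))
  diag(r) <- 1
  attr(r, "zero_variance") <- flagged
  r
}

#' Remove redundant features by Pearson threshold and MIC
#'
#' Groups features whose absolute pairwise Pearson correlation exceeds
#' `r_threshold` (transitive closure of the threshold graph) and keeps, per
#' group, only the member with the highest MIC against the target; MIC ties
#' are broken by lexicographic feature name. Zero-variance columns are
#' dropped first.
#'
#' @param x Feature matrix or data frame.
#' @param target Label vector aligned with the rows (the classification
#'   target).
#' @param r_threshold Absolute-correlation threshold (default 0.65).
#' @param alpha MIC grid-bound exponent passed to [mic()].
#' @return Reduced [feature_matrix()]; removed columns are recorded in the
#'   `removed` attribute.
#' @export
dedupe_features <- function(x, target, r_threshold = 0.65, alpha = 0.6) {
  fm <- drop_zero_variance(x)
  y <- as.numeric(factor(target))
  stopifnot(length(y) == nrow(fm))
  nms <- names(fm)
  if (length(nms) < 2) return(fm)
  r <- pairwise_correlation(fm)
  adj <- abs(r) > r_threshold
  diag(adj) <- FALSE
  # connected components of the redundancy graph
  comp <- rep(NA_integer_, length(nms))
  cid <- 0L
  for (i in seq_along(nms)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  keep <- character(0)
  for (g in unique(comp)) {
    members <- nms[comp == g]
    if (length(members) == 1) {
      keep <- c(keep, members)
      next
    }
    mics <- vapply(members, function(nm) {
      suppressWarnings(mic(as.numeric(fm[[nm]]), y, alpha = alpha))
    }, numeric(1))
    ord <- order(-mics, members)
    keep <- c(keep, members[ord[1]])
  }
  keep <- nms[nms %in% keep]
  out <- .fm_subset(fm, keep)
  attr(out, "removed") <- setdiff(nms, keep)
  out
}

#' Append two-way interaction features
#'
#' For every unordered pair of columns appends a product column
#' (`A_x_B`, synergy: risk tied to joint change in the same direction) and a
#' quotient column (`A_div_B`, divergence: risk tied to change in opposite
#' directions). Quotients are computed on min-max-scaled inputs as
#' `A' / (B' + 1e-6)` so no division by zero can occur; the reverse
#' orientation `B_div_A` is also generated unless it correlates with the
#' forward one beyond `r_threshold` in absolute value, in which case only
#' the lexicographically first orientation is kept.
#'
#' @param x Feature matrix or data frame of numeric columns.
#' @param mode `"none"` (identity) or `"two_way"`.
#' @param r_threshold Redundancy threshold for the two quotient orientations.
#' @return [feature_matrix()] with interaction columns appended, each with
#'   provenance recording both parents.
#' @export
build_interactions <- function(x, mode = c("none", "two_way"),
                               r_threshold = 0.65) {
  mode <- match.arg(mode)
  fm <- if (inherits(x, "feature_matrix")) x else feature_matrix(x)
  if (mode == "none") return(fm)
  df <- as.data.frame(fm)
  prov <- provenance(fm)
  base <- names(df)
  scale01 <- function(v) {
    v <- as.numeric(v)
    rng <- range(v)
    if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else rep(0, length(v))
  }
  scaled <- lapply(df, scale01)
  for (i in seq_along(base)) {
    for (j in seq_along(base)) {
      if (j <= i) next
      a <- base[i]; b <- base[j]
      pn <- paste0(a, "_x_", b)
      df[[pn]] <- as.numeric(df[[a]]) * as.numeric(df[[b]])
      prov[[pn]] <- list(type = "product", parents = c(a, b))
      q1 <- scaled[[a]] / (scaled[[b]] + 1e-6)
      q2 <- scaled[[b]] / (scaled[[a]] + 1e-6)
      qn1 <- paste0(a, "_div_", b)
      df[[qn1]] <- q1
      prov[[qn1]] <- list(type = "quotient", parents = c(a, b),
                          ranges = list(range(as.numeric(df[[a]])),
                                        range(as.numeric(df[[b]]))))
      r_q <- if (stats::sd(q1) > 0 && stats::sd(q2) > 0) {
        stats::cor(q1, q2)
      } else 1
      if (abs(r_q) <= r_threshold) {
        qn2 <- paste0(b, "_div_", a)
        df[[qn2]] <- q2
        prov[[qn2]] <- list(type = "quotient", parents = c(b, a),
                            ranges = list(range(as.numeric(df[[b]])),
                                          range(as.numeric(df[[a]]))))
      }
    }
  }
  feature_matrix(df, prov)
}
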