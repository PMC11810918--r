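# Phenotype discovery: embed the three totals, cluster the embedding,
# validate with silhouette, attach deterministic phenotype names.

#' Mean silhouette of a clustering
#'
#' Mean silhouette width over non-noise points (noise label 0 is excluded
#' from both the averaged points and the candidate neighboring clusters).
#'
#' @param x Numeric matrix the distances are computed on (embedding or
#'   score matrix).
#' @param labels Integer cluster labels, `0` = noise.
#' @return Mean silhouette width in \[-1, 1\].
#' @export
evaluate_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels))
  mask <- labels != 0
  lab <- labels[mask]
  if (length(unique(lab)) < 2) {
    stop("silhouette undefined with fewer than 2 non-noise clusters",
         call. = FALSE)
  }
  sil <- cluster::silhouette(as.integer(factor(lab)),
                             dist = stats::dist(x[mask, , drop = FALSE]))
  mean(sil[, "sil_width"])
}

#' Phenotype names used by the labeling rubric
#' @return Character vector of the possible phenotype names.
#' @export
phenotype_names <- function() {
  c("PTSD", "anxiety", "mixed_anxiety_depression", "minimal_symptom",
    "unlabeled")
}

#' Deterministic phenotype labeling of a cluster solution
#'
#' Applies a fixed rubric to the per-cluster mean totals:
#' clusters are ranked by mean PCL-C descending; the first cluster at or
#' above the PTSD screening threshold is named `PTSD`; among the remaining
#' clusters the one with the lowest aggregate elevation (mean of the three
#' totals rescaled to their instrument ranges) is `minimal_symptom`; when the
#' solution has exactly four clusters the remaining two are split by BAI mean
#' (`anxiety` above, `mixed_anxiety_depression` below). With a cluster count
#' other than four, clusters not covered by the rubric are `unlabeled`,
#' never dropped.
#'
#' @param summaries Data frame with one row per cluster: columns `cluster`,
#'   `bai_mean`, `phq9_mean`, `pclc_mean` (as produced by
#'   [phenotype_clustering()]).
#' @param ptsd_threshold PCL-C screening threshold (default 33).
#' @return Named character vector: phenotype name per cluster id.
#' @export
label_phenotypes <- function(summaries, ptsd_threshold = 33) {
  stopifnot(all(c("cluster", "bai_mean", "phq9_mean", "pclc_mean") %in%
                  names(summaries)))
  k <- nrow(summaries)
  out <- stats::setNames(rep("unlabeled", k), summaries$cluster)
  if (k == 0) return(out)
  elev <- function(i) {
    mean(c(summaries$bai_mean[i] / 63,
           summaries$phq9_mean[i] / 27,
           (summaries$pclc_mean[i] - 17) / 68))
  }
  ord <- order(-summaries$pclc_mean, summaries$cluster)
  remaining <- ord
  if (summaries$pclc_mean[ord[1]] >= ptsd_threshold) {
    out[ord[1]] <- "PTSD"
    remaining <- setdiff(remaining, ord[1])
  }
  if (length(remaining) > 0) {
    agg <- vapply(remaining, elev, numeric(1))
    low <- remaining[which.min(agg)]
    out[low] <- "minimal_symptom"
    remaining <- setdiff(remaining, low)
  }
  if (k == 4 && length(remaining) == 2) {
    hi_bai <- remaining[which.max(summaries$bai_mean[remaining])]
    out[hi_bai] <- "anxiety"
    out[setdiff(remaining, hi_bai)] <- "mixed_anxiety_depression"
  }
  out
}

#' Discover mental-health phenotypes from total scores
#'
#' Runs the phenotyping clustering pipeline on a scored cohort: standardize
#' and embed the BAI/PHQ-9/PCL-C totals, cluster the embedding with HDBSCAN,
#' summarize the clusters, compute the silhouette on the embedding, and name
#' the phenotypes with the deterministic rubric.
#'
#' @param scored Data frame with `bai_total`, `phq9_total`, `pclc_total`
#'   (e.g. from [score_cohort()] or [generate_cohort()] + [score_cohort()]).
#' @param embed_config An [embedding_config()]; its seed drives every
#'   stochastic step.
#' @param min_cluster_size Minimum dense-region size; default
#'   `max(10, ceiling(0.08 * n))`. Integer questionnaire totals produce
#'   heavily duplicated rows; smaller minima let small groups of
#'   near-duplicates surface as spurious micro-clusters.
#' @param min_samples Core-distance order; defaults to `min_cluster_size`.
#' @param reassign_noise If `TRUE`, noise points are attached to the nearest
#'   cluster centroid (in the embedding) after selection; default keeps
#'   noise separate.
#' @param ptsd_threshold Threshold passed to [label_phenotypes()].
#' @return Object of class `cluster_solution`: list with `labels` (0 =
#'   noise), `embedding`, `cluster_sizes`, `summaries` (per-cluster mean/SD
#'   of the three totals), `silhouette`, `phenotypes` (id -> name),
#'   `phenotype` (per-participant name, `"noise"` for noise), `config`.
#' @export
phenotype_clustering <- function(scored,
                                 embed_config = embedding_config(),
                                 min_cluster_size = NULL,
                                 min_samples = NULL,
                                 reassign_noise = FALSE,
                                 ptsd_threshold = 33) {
  need <- c("bai_total", "phq9_total", "pclc_total")
  stopifnot(all(need %in% names(scored)))
  scores <- as.matrix(scored[, need])
  n <- nrow(scores)
  if (is.null(min_cluster_size)) min_cluster_size <- max(10L, ceiling(0.08 * n))
  if (is.null(min_samples)) min_samples <- min_cluster_size
  emb <- embed_scores(scores, embed_config)
  labels <- cluster_embedding(emb, min_cluster_size, min_samples)
  if (reassign_noise && any(labels == 0) && any(labels != 0)) {
    ids <- sort(unique(labels[labels != 0]))
    cent <- t(vapply(ids, function(id) {
      colMeans(emb[labels == id, , drop = FALSE])
    }, numeric(ncol(emb))))
    for (i in which(labels == 0)) {
      d2 <- rowSums((cent - matrix(emb[i, ], nrow(cent), ncol(emb),
                                   byrow = TRUE))^2)
      labels[i] <- ids[which.min(d2)]
    }
  }
  ids <- sort(unique(labels[labels != 0]))
  summaries <- do.call(rbind, lapply(ids, function(id) {
    sel <- labels == id
    data.frame(cluster = id, n = sum(sel),
               bai_mean = mean(scored$bai_total[sel]),
               bai_sd = stats::sd(scored$bai_total[sel]),
               phq9_mean = mean(scored$phq9_total[sel]),
               phq9_sd = stats::sd(scored$phq9_total[sel]),
               pclc_mean = mean(scored$pclc_total[sel]),
               pclc_sd = stats::sd(scored$pclc_total[sel]))
  }))
  if (is.null(summaries)) {
    summaries <- data.frame(cluster = integer(0), n = integer(0),
                            bai_mean = numeric(0), bai_sd = numeric(0),
                            phq9_mean = numeric(0), phq9_sd = numeric(0),
                            pclc_mean = numeric(0), pclc_sd = numeric(0))
  }
  sil <- if (length(ids) >= 2) evaluate_silhouette(emb, labels) else NA_real_
  phen <- label_phenotypes(summaries, ptsd_threshold)
  per_part <- rep("noise", n)
  for (id in ids) per_part[labels == id] <- phen[[as.character(id)]]
  sizes <- stats::setNames(
    vapply(ids, function(id) sum(labels == id), integer(1)),
    as.character(ids))
  if (any(labels == 0)) sizes <- c(sizes, noise = sum(labels == 0))
  structure(list(labels = labels, embedding = emb, cluster_sizes = sizes,
                 summaries = summaries, silhouette = sil,
                 phenotypes = phen, phenotype = per_part,
                 config = list(embed = embed_config,
                               min_cluster_size = min_cluster_size,
                               min_samples = min_samples,
                               reassign_noise = reassign_noise,
                               ptsd_threshold = ptsd_threshold,
                               seed = embed_config$seed)),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  k <- sum(names(x$cluster_sizes) != "noise")
  cat(sprintf("<cluster_solution> %d clusters over %d participants", k,
              length(x$labels)))
  if ("noise" %in% names(x$cluster_sizes)) {
    cat(sprintf(" (%d noise)", x$cluster_sizes[["noise"]]))
  }
  cat(sprintf("; silhouette = %s\n",
              if (is.na(x$silhouette)) "NA" else sprintf("%.3f", x$silhouette)))
  if (nrow(x$summaries) > 0) {
    df <- x$summaries
    df$phenotype <- x$phenotypes[as.character(df$cluster)]
    print(df, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
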