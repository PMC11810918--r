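# Nonlinear dimension reduction of the three symptom totals: a compact UMAP
# implementation (fuzzy simplicial set from smoothed kNN distances, PCA
# initialization, SGD layout with negative sampling).

#' @useDynLib mhpheno, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Embedding configuration
#'
#' Parameters of the nonlinear dimension-reduction step applied to the
#' standardized total-score matrix before density clustering.
#'
#' @param n_components Output dimensionality (default 2).
#' @param n_neighbors Size of the local neighborhood used to estimate the
#'   manifold (default 15).
#' @param min_dist Minimum distance between points in the layout (default 0.1).
#' @param metric Distance metric; only `"euclidean"` is supported.
#' @param seed Integer seed controlling initialization and the stochastic
#'   layout (default 42).
#' @param standardize_inputs Z-score the input columns first. Default
#'   `FALSE`: questionnaire totals are kept in raw score units so that all
#'   three instruments share the same ordinal lattice spacing; z-scoring
#'   makes the lattice of the widest-range instrument several times finer
#'   than the others, leaving between-phenotype gaps smaller than
#'   within-phenotype lattice gaps.
#' @param n_epochs Number of layout optimization epochs (default 500, the
#'   reference small-data setting).
#' @param spread Scale of the embedded point cloud (default 1).
#' @param dedup_jitter SD of seeded Gaussian jitter added to the
#'   (standardized) inputs before neighbor search (default 0.05). Integer
#'   total scores produce exactly duplicated rows whose zero distances make
#'   density estimates degenerate; a jitter well below the lattice spacing
#'   breaks the ties without moving points across score levels. Set to 0 to
#'   disable.
#' @return Object of class `embedding_config`.
#' @export
embedding_config <- function(n_components = 2L, n_neighbors = 15L,
                             min_dist = 0.1, metric = "euclidean",
                             seed = 42L, standardize_inputs = FALSE,
                             n_epochs = 500L, spread = 1.0,
                             dedup_jitter = 0.05) {
  stopifnot(n_components >= 1, n_neighbors >= 2)
  if (!identical(metric, "euclidean")) {
    stop("only the euclidean metric is supported", call. = FALSE)
  }
  structure(list(n_components = as.integer(n_components),
                 n_neighbors = as.integer(n_neighbors),
                 min_dist = min_dist, metric = metric,
                 seed = as.integer(seed),
                 standardize_inputs = isTRUE(standardize_inputs),
                 n_epochs = as.integer(n_epochs), spread = spread,
                 dedup_jitter = dedup_jitter),
            class = "embedding_config")
}

# Fit the a, b parameters of the low-dimensional similarity curve
# 1/(1 + a d^(2b)) to the target exp(-(d - min_dist)/spread) beyond min_dist.
.find_ab <- function(min_dist, spread) {
  d <- seq(0, 3 * spread, length.out = 300)
  target <- ifelse(d < min_dist, 1, exp(-(d - min_dist) / spread))
  obj <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    sum((1 / (1 + a * d^(2 * b)) - target)^2)
  }
  fit <- stats::optim(c(log(1.6), log(0.9)), obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  c(a = exp(fit$par[1]), b = exp(fit$par[2]))
}

# Eigenvectors of the symmetrized normalized graph Laplacian belonging to
# the smallest non-trivial eigenvalues, as layout initialization.
.spectral_init <- function(head, tail, w, n, n_components) {
  A <- matrix(0, n, n)
  A[cbind(head, tail)] <- w
  A[cbind(tail, head)] <- w
  deg <- rowSums(A)
  if (any(deg <= 0)) stop("isolated vertex")
  dinv <- 1 / sqrt(deg)
  L <- diag(n) - (dinv * A) * rep(dinv, each = n)
  ev <- eigen(L, symmetric = TRUE)
  ord <- order(ev$values)
  # drop the trivial constant eigenvector
  take <- ord[seq(2, 1 + n_components)]
  init <- ev$vectors[, take, drop = FALSE]
  if (any(!is.finite(init))) stop("non-finite eigenvectors")
  init
}

# Smoothed kNN calibration: per-point connectivity bandwidth sigma such that
# sum_j exp(-max(0, d_ij - rho_i)/sigma_i) = log2(k), rho_i = nearest
# positive neighbor distance.
.smooth_knn <- function(knn_dist, n_iter = 64L, tol = 1e-5) {
  k <- ncol(knn_dist)
  target <- log2(k)
  n <- nrow(knn_dist)
  rho <- numeric(n)
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    di <- knn_dist[i, ]
    pos <- di[di > 0]
    rho[i] <- if (length(pos) > 0) min(pos) else 0
    lo <- 0; hi <- Inf; mid <- 1
    for (it in seq_len(n_iter)) {
      val <- sum(exp(-pmax(0, di - rho[i]) / mid))
      if (abs(val - target) < tol) break
      if (val > target) {
        hi <- mid; mid <- (lo + hi) / 2
      } else {
        lo <- mid
        mid <- if (is.finite(hi)) (lo + hi) / 2 else mid * 2
      }
    }
    sigma[i] <- max(mid, 1e-12)
  }
  list(rho = rho, sigma = sigma)
}

#' Embed a total-score matrix
#'
#' Computes a low-dimensional embedding of the per-participant total-score
#' matrix (columns: BAI, PHQ-9, PCL-C totals, or any numeric features):
#' exact k-nearest neighbors, smoothed-kNN fuzzy simplicial set with
#' probabilistic t-conorm symmetrization, PCA initialization, and stochastic
#' gradient layout optimization. Deterministic given `config$seed`; row order
#' is preserved.
#'
#' @param score_matrix Numeric matrix or data frame, one row per participant.
#' @param config An [embedding_config()].
#' @return Numeric matrix `n x n_components` with attribute `config`.
#' @export
embed_scores <- function(score_matrix, config = embedding_config()) {
  stopifnot(inherits(config, "embedding_config"))
  x <- as.matrix(score_matrix)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("score matrix contains missing values", call. = FALSE)
  n <- nrow(x)
  if (n <= config$n_neighbors) {
    stop(sprintf("need more rows (%d) than n_neighbors (%d)", n,
                 config$n_neighbors), call. = FALSE)
  }
  if (config$standardize_inputs) {
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0] <- 1
    x <- scale(x, center = TRUE, scale = sds)
  }
  set.seed(config$seed)
  if (!is.null(config$dedup_jitter) && config$dedup_jitter > 0) {
    x <- x + matrix(stats::rnorm(length(x), 0, config$dedup_jitter),
                    nrow(x), ncol(x))
  }
  k <- config$n_neighbors
  dm <- as.matrix(stats::dist(x))
  knn_idx <- matrix(0L, n, k)
  knn_dist <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ord <- order(dm[i, ], seq_len(n))     # ties broken by index: deterministic
    ord <- ord[ord != i][seq_len(k)]
    knn_idx[i, ] <- ord
    knn_dist[i, ] <- dm[i, ord]
  }
  sk <- .smooth_knn(knn_dist)
  w <- exp(-pmax(0, sweep(knn_dist, 1, sk$rho)) / sk$sigma)

  # directed edges -> fuzzy union w + w' - w w'
  head <- rep(seq_len(n), each = k)
  tail <- as.vector(t(knn_idx))
  wt <- as.vector(t(w))
  key <- (head - 1) * n + tail
  rev_key <- (tail - 1) * n + head
  m <- match(rev_key, key)
  w_rev <- ifelse(is.na(m), 0, wt[m])
  w_sym <- wt + w_rev - wt * w_rev
  keep <- head < tail | is.na(m)          # one undirected edge per pair
  head_u <- head[keep]; tail_u <- tail[keep]; w_u <- w_sym[keep]
  pos <- w_u > max(w_u) / config$n_epochs
  head_u <- head_u[pos]; tail_u <- tail_u[pos]; w_u <- w_u[pos]

  ab <- .find_ab(config$min_dist, config$spread)

  # spectral initialization from the symmetrized fuzzy graph (normalized
  # Laplacian eigenvectors), falling back to PCA if the graph is
  # degenerate; scaled to a 10-unit radius
  init <- tryCatch(
    .spectral_init(head_u, tail_u, w_u, n, config$n_components),
    error = function(e) NULL)
  if (is.null(init)) {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    d_avail <- min(config$n_components, ncol(pc$x))
    init <- matrix(0, n, config$n_components)
    init[, seq_len(d_avail)] <- pc$x[, seq_len(d_avail), drop = FALSE]
  }
  rad <- max(abs(init))
  if (rad > 0) init <- init * (10 / rad)
  init <- init + matrix(stats::rnorm(n * config$n_components, 0, 1e-4),
                        n, config$n_components)

  emb <- .umap_layout_cpp(init, as.integer(head_u - 1L),
                          as.integer(tail_u - 1L),
                          max(w_u) / w_u,
                          ab[["a"]], ab[["b"]], gamma = 1.0,
                          initial_alpha = 1.0,
                          n_epochs = config$n_epochs,
                          negative_sample_rate = 5.0,
                          seed = config$seed)
  dimnames(emb) <- list(rownames(score_matrix),
                        paste0("dim", seq_len(config$n_components)))
  attr(emb, "config") <- config
  emb
}
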