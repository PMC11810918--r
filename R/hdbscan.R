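# Hierarchical density-based clustering (HDBSCAN): mutual-reachability
# distances, minimum spanning tree, single-linkage hierarchy, condensed tree
# under a minimum cluster size, excess-of-mass cluster selection, noise
# labeling. Noise points carry label 0.

# Prim's MST on a dense distance matrix; returns edges (from, to, weight).
.mst_edges <- function(dm) {
  n <- nrow(dm)
  in_tree <- logical(n)
  best <- rep(Inf, n)
  parent <- integer(n)
  in_tree[1] <- TRUE
  best_upd <- dm[1, ]
  upd <- best_upd < best
  best[upd] <- best_upd[upd]
  parent[upd] <- 1L
  from <- integer(n - 1); to <- integer(n - 1); wt <- numeric(n - 1)
  for (e in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    in_tree[v] <- TRUE
    from[e] <- parent[v]; to[e] <- v; wt[e] <- best[v]
    upd <- !in_tree & dm[v, ] < best
    best[upd] <- dm[v, upd]
    parent[upd] <- v
  }
  data.frame(from = from, to = to, weight = wt)
}

# Single-linkage merge tree from sorted MST edges via union-find.
# Returns, per internal node: children (node ids; leaves 1..n, internal
# n+1..2n-1), merge height, subtree leaf count.
.linkage_tree <- function(edges, n) {
  ord <- order(edges$weight, edges$from, edges$to)
  parent_uf <- seq_len(2L * n - 1L)
  root_of <- function(v) {
    while (parent_uf[v] != v) {
      parent_uf[v] <<- parent_uf[parent_uf[v]]
      v <- parent_uf[v]
    }
    v
  }
  child_l <- integer(n - 1); child_r <- integer(n - 1)
  height <- numeric(n - 1); size <- integer(2L * n - 1L)
  size[1:n] <- 1L
  nxt <- n
  for (e in ord) {
    ra <- root_of(edges$from[e]); rb <- root_of(edges$to[e])
    nxt <- nxt + 1L
    child_l[nxt - n] <- ra; child_r[nxt - n] <- rb
    height[nxt - n] <- edges$weight[e]
    size[nxt] <- size[ra] + size[rb]
    parent_uf[ra] <- nxt; parent_uf[rb] <- nxt
  }
  list(child_l = child_l, child_r = child_r, height = height, size = size, n = n)
}

.leaves_under <- function(tree, node) {
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= tree$n) out <- c(out, v) else {
      stack <- c(stack, tree$child_l[v - tree$n], tree$child_r[v - tree$n])
    }
  }
  out
}

# Condense the single-linkage hierarchy: clusters persist while splits shed
# sub-minimum-size components; a split into two large components creates two
# child clusters. lambda = 1/height (capped for zero heights).
.condense_tree <- function(tree, min_cluster_size) {
  n <- tree$n
  lam <- function(h) 1 / max(h, 1e-10)
  clusters <- list()
  new_cluster <- function(parent, birth) {
    clusters[[length(clusters) + 1L]] <<- list(
      parent = parent, birth = birth, children = integer(0),
      points = integer(0), point_lambda = numeric(0), death = NA_real_,
      split_mass = 0L)
    length(clusters)
  }
  root_node <- 2L * n - 1L
  root_id <- new_cluster(NA_integer_, lam(tree$height[root_node - n]))
  # stack of (tree node, cluster id)
  stack_node <- root_node
  stack_cl <- root_id
  while (length(stack_node) > 0) {
    v <- stack_node[length(stack_node)]; cid <- stack_cl[length(stack_cl)]
    stack_node <- stack_node[-length(stack_node)]
    stack_cl <- stack_cl[-length(stack_cl)]
    # walk down from v within cluster cid
    repeat {
      if (v <= n) {  # single point remains: falls out at its own lambda
        clusters[[cid]]$points <- c(clusters[[cid]]$points, v)
        clusters[[cid]]$point_lambda <- c(clusters[[cid]]$point_lambda, Inf)
        clusters[[cid]]$death <- Inf
        break
      }
      iv <- v - n
      l <- tree$child_l[iv]; r <- tree$child_r[iv]
      lv <- lam(tree$height[iv])
      nl <- tree$size[l]; nr <- tree$size[r]
      big_l <- nl >= min_cluster_size
      big_r <- nr >= min_cluster_size
      if (big_l && big_r) {
        clusters[[cid]]$death <- lv
        clusters[[cid]]$split_mass <- nl + nr
        cl <- new_cluster(cid, lv); cr <- new_cluster(cid, lv)
        clusters[[cid]]$children <- c(cl, cr)
        stack_node <- c(stack_node, l, r)
        stack_cl <- c(stack_cl, cl, cr)
        break
      }
      if (!big_l && !big_r) {  # cluster dies; all remaining points fall out
        pts <- .leaves_under(tree, v)
        clusters[[cid]]$points <- c(clusters[[cid]]$points, pts)
        clusters[[cid]]$point_lambda <- c(clusters[[cid]]$point_lambda,
                                          rep(lv, length(pts)))
        clusters[[cid]]$death <- lv
        break
      }
      small <- if (big_l) r else l
      pts <- .leaves_under(tree, small)
      clusters[[cid]]$points <- c(clusters[[cid]]$points, pts)
      clusters[[cid]]$point_lambda <- c(clusters[[cid]]$point_lambda,
                                        rep(lv, length(pts)))
      v <- if (big_l) l else r
    }
  }
  clusters
}

# Excess-of-mass selection; the root cluster is never selectable.
.select_clusters <- function(clusters) {
  n_cl <- length(clusters)
  stability <- numeric(n_cl)
  for (i in seq_len(n_cl)) {
    cl <- clusters[[i]]
    lam_fall <- pmin(cl$point_lambda, 1e12)
    stability[i] <- sum(lam_fall - cl$birth)
    if (cl$split_mass > 0) {
      stability[i] <- stability[i] +
        cl$split_mass * (min(cl$death, 1e12) - cl$birth)
    }
  }
  selected <- logical(n_cl)
  subtree_score <- numeric(n_cl)
  # process children before parents (children always have larger ids);
  # the root (cluster 1) is never selected, its score is its children's sum
  for (i in rev(seq_len(n_cl))) {
    cl <- clusters[[i]]
    if (i == 1L && length(cl$children) > 0) {
      subtree_score[i] <- sum(subtree_score[cl$children])
    } else if (length(cl$children) == 0) {
      selected[i] <- i != 1L
      subtree_score[i] <- stability[i]
    } else {
      child_sum <- sum(subtree_score[cl$children])
      if (stability[i] >= child_sum) {
        selected[i] <- TRUE
        subtree_score[i] <- stability[i]
      } else {
        subtree_score[i] <- child_sum
      }
    }
  }
  # deselect descendants of selected ancestors (top-down)
  for (i in seq_len(n_cl)) {
    if (!selected[i]) next
    desc <- clusters[[i]]$children
    while (length(desc) > 0) {
      selected[desc] <- FALSE
      desc <- unlist(lapply(clusters[desc], `[[`, "children"))
    }
  }
  selected
}

#' Density-based clustering of an embedding
#'
#' HDBSCAN clustering: mutual-reachability distances with the given
#' `min_samples` core-distance order, minimum spanning tree, condensed
#' cluster hierarchy under `min_cluster_size`, and excess-of-mass cluster
#' selection. Points in no selected dense region are labeled `0` (noise).
#' Cluster ids `1..K` are assigned in decreasing cluster size (ties broken
#' by smallest member index).
#'
#' @param embedding Numeric matrix of coordinates (or any numeric features).
#' @param min_cluster_size Smallest size a dense region must reach to count
#'   as a cluster.
#' @param min_samples Neighborhood order of the core distance; defaults to
#'   `min_cluster_size`.
#' @return Integer vector of labels, `0` = noise, with attribute
#'   `n_clusters`.
#' @export
cluster_embedding <- function(embedding, min_cluster_size = 10L,
                              min_samples = min_cluster_size) {
  x <- as.matrix(embedding)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("embedding must be finite", call. = FALSE)
  n <- nrow(x)
  stopifnot(min_cluster_size >= 2, min_samples >= 1, n >= 2)
  dm <- as.matrix(stats::dist(x))
  k <- min(min_samples, n - 1L)
  core <- apply(dm, 1, function(row) sort(row, partial = k + 1)[k + 1])
  mrd <- pmax(dm, outer(core, rep(1, n)), outer(rep(1, n), core))
  diag(mrd) <- 0
  edges <- .mst_edges(mrd)
  tree <- .linkage_tree(edges, n)
  clusters <- .condense_tree(tree, min_cluster_size)
  selected <- .select_clusters(clusters)
  labels <- integer(n)
  sel_ids <- which(selected)
  members <- lapply(sel_ids, function(i) {
    pts <- clusters[[i]]$points
    desc <- clusters[[i]]$children
    while (length(desc) > 0) {
      pts <- c(pts, unlist(lapply(clusters[desc], `[[`, "points")))
      desc <- unlist(lapply(clusters[desc], `[[`, "children"))
    }
    sort(pts)
  })
  if (length(members) > 0) {
    ord <- order(-vapply(members, length, integer(1)),
                 vapply(members, function(p) if (length(p)) min(p) else n + 1L,
                        integer(1)))
    for (new_id in seq_along(ord)) {
      labels[members[[ord[new_id]]]] <- new_id
    }
  }
  structure(labels, n_clusters = length(sel_ids))
}
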