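# Gradient-boosted classification of the PTSD phenotype vs the
# minimal-symptom phenotype: repeated stratified cross-validated F1,
# saturation-based greedy forward feature selection, partial dependence and
# pairwise interaction probability surfaces. The boosting engine (gradient-
# boosted decision trees with logistic loss, sigmoid link, 0.5 decision
# boundary) sits behind a model-config contract.

#' Boosted-model configuration
#'
#' Hyperparameters of the gradient-boosted tree ensemble with logistic loss.
#'
#' @param nrounds Number of boosting iterations (default 50).
#' @param max_depth Tree depth (default 3).
#' @param eta Learning rate (default 0.3).
#' @param min_child_weight Minimum hessian per leaf (default 1).
#' @return Object of class `boost_config`.
#' @export
boost_config <- function(nrounds = 50L, max_depth = 3L, eta = 0.3,
                         min_child_weight = 1) {
  structure(list(nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
                 eta = eta, min_child_weight = min_child_weight),
            class = "boost_config")
}

.as_feature_num_matrix <- function(features) {
  df <- as.data.frame(features)
  m <- vapply(df, function(col) as.numeric(col), numeric(nrow(df)))
  m <- matrix(m, nrow = nrow(df),
              dimnames = list(NULL, names(df)))
  m
}

.as_binary_label <- function(labels, positive = NULL) {
  f <- factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly two classes", call. = FALSE)
  if (is.null(positive)) positive <- levels(f)[2]
  if (!positive %in% levels(f)) stop("positive class not present", call. = FALSE)
  list(y = as.integer(f == positive), positive = positive)
}

#' Fit the boosted classifier
#'
#' @param features Feature matrix / data frame of numeric columns.
#' @param labels Two-class label vector.
#' @param config A [boost_config()].
#' @param positive Positive class (default: second factor level).
#' @param seed Integer seed for the booster.
#' @return Object of class `mh_boost` wrapping the fitted ensemble; predict
#'   with [predict_prob()].
#' @export
fit_boost <- function(features, labels, config = boost_config(),
                      positive = NULL, seed = 1L) {
  m <- .as_feature_num_matrix(features)
  lab <- .as_binary_label(labels, positive)
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(m, label = lab$y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = config$max_depth,
                  eta = config$eta, min_child_weight = config$min_child_weight,
                  tree_method = "exact", nthread = 1, seed = seed),
    data = dtrain, nrounds = config$nrounds, verbose = 0)
  structure(list(booster = booster, feature_names = colnames(m),
                 positive = lab$positive, config = config),
            class = "mh_boost")
}

#' Predicted positive-class probabilities
#'
#' Probabilities from the logistic link (sigmoid of the boosted raw score);
#' class membership is probability > 0.5.
#'
#' @param model An [fit_boost()] model.
#' @param features Feature data with the model's columns.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_prob <- function(model, features) {
  stopifnot(inherits(model, "mh_boost"))
  m <- .as_feature_num_matrix(as.data.frame(features)[, model$feature_names,
                                                      drop = FALSE])
  as.numeric(stats::predict(model$booster,
                            xgboost::xgb.DMatrix(m, nthread = 1)))
}

#' F1 score
#'
#' Harmonic mean of precision (positive predictive value) and recall
#' (sensitivity) for the designated positive class. Returns 0 when no
#' positives are predicted or no true positives are recovered.
#'
#' @param truth True labels.
#' @param predicted Predicted labels (same coding).
#' @param positive Positive class.
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(truth, predicted, positive) {
  tp <- sum(truth == positive & predicted == positive)
  fp <- sum(truth != positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  if (tp == 0) return(0)
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  2 * precision * recall / (precision + recall)
}

# Stratified fold assignment: shuffles within each class, then deals fold
# ids round-robin.
.stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Repeated cross-validated F1 of the boosted classifier
#'
#' Stratified k-fold cross-validation repeated `repeats` times (default
#' 5 x 5 = 25 trials). Per trial, the booster is fit on the training folds
#' and the F1 of the designated positive class is computed on the held-out
#' fold at the 0.5 probability boundary.
#'
#' @param features Feature matrix / data frame.
#' @param labels Two-class labels.
#' @param config A [boost_config()].
#' @param folds,repeats Cross-validation design (defaults 5 and 5).
#' @param seed Integer seed; per-repeat fold seeds are derived
#'   deterministically.
#' @param positive Positive class (default second factor level).
#' @return List with `mean`, `sd`, `per_trial` (length `folds * repeats`).
#' @export
cv_f1 <- function(features, labels, config = boost_config(), folds = 5L,
                  repeats = 5L, seed = 1L, positive = NULL) {
  m <- .as_feature_num_matrix(features)
  lab <- .as_binary_label(labels, positive)
  y <- lab$y
  if (min(table(y)) < folds) {
    stop("too few members of a class to stratify across folds", call. = FALSE)
  }
  per_trial <- numeric(0)
  for (rep_i in seq_len(repeats)) {
    set.seed(seed + 7919L * rep_i)
    fold_id <- .stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2) {
        stop("fold lacks a class; stratification failed", call. = FALSE)
      }
      model <- fit_boost(m[tr, , drop = FALSE], y[tr], config,
                         positive = 1, seed = seed + 7919L * rep_i + f)
      p <- predict_prob(model, m[!tr, , drop = FALSE])
      per_trial <- c(per_trial, f1_score(y[!tr], as.integer(p > 0.5), 1))
    }
  }
  list(mean = mean(per_trial), sd = stats::sd(per_trial),
       per_trial = per_trial)
}

#' Greedy forward feature selection under the saturation rule
#'
#' Builds the model one feature at a time. At each step every remaining
#' candidate is scored by cross-validated F1 of the current set plus the
#' candidate (a cheap screening pass with `screen_repeats` repeats); the
#' `screen_top` best-screening candidates are then re-evaluated with the
#' full repeated CV (`folds x repeats` trials), the best of them by full
#' mean F1 is the step's candidate, and it is kept only if its mean-F1 gain
#' over the current model exceeds `saturation_sd` times the reference
#' model's F1 SD (model saturation). The reference is the current best
#' model (`base = "current"`) or the first one-feature model
#' (`base = "first"`).
#'
#' @param features Feature matrix / data frame (typically after
#'   [dedupe_features()]).
#' @param labels Two-class labels.
#' @param max_features Upper bound on the selected set (default 10).
#' @param saturation_sd Saturation multiplier (default 1).
#' @param config A [boost_config()].
#' @param folds,repeats Full-CV design for the saturation decision.
#' @param screen_repeats Repeats used in the per-candidate screening pass
#'   (default 1).
#' @param screen_top Number of top screening candidates re-evaluated with
#'   the full CV at each step (default 3).
#' @param base `"current"` or `"first"`.
#' @param seed Integer seed.
#' @param positive Positive class.
#' @return List with `features` (selected names in order), `trace` (data
#'   frame: step, candidate, mean_f1, sd_f1, decision), `mean`, `sd`,
#'   `per_trial` for the final model.
#' @export
select_features <- function(features, labels, max_features = 10L,
                            saturation_sd = 1.0, config = boost_config(),
                            folds = 5L, repeats = 5L, screen_repeats = 1L,
                            screen_top = 3L,
                            base = c("current", "first"), seed = 1L,
                            positive = NULL) {
  base <- match.arg(base)
  df <- as.data.frame(features)
  if (ncol(df) == 0) stop("empty feature pool", call. = FALSE)
  pool <- names(df)
  selected <- character(0)
  trace <- list()
  current <- NULL
  first_sd <- NA_real_
  step <- 0L
  while (length(selected) < max_features && length(pool) > 0) {
    step <- step + 1L
    screen <- vapply(pool, function(cand) {
      cv_f1(df[, c(selected, cand), drop = FALSE], labels, config,
            folds = folds, repeats = screen_repeats,
            seed = seed + 131L * step, positive = positive)$mean
    }, numeric(1))
    ord <- order(-screen, pool)
    shortlist <- pool[ord[seq_len(min(screen_top, length(pool)))]]
    fulls <- lapply(shortlist, function(cand) {
      cv_f1(df[, c(selected, cand), drop = FALSE], labels, config,
            folds = folds, repeats = repeats, seed = seed,
            positive = positive)
    })
    best_i <- order(-vapply(fulls, `[[`, numeric(1), "mean"), shortlist)[1]
    cand <- shortlist[best_i]
    full <- fulls[[best_i]]
    if (step == 1L) {
      first_sd <- full$sd
      decision <- "kept"
    } else {
      ref_sd <- if (base == "current") current$sd else first_sd
      gain <- full$mean - current$mean
      decision <- if (gain > saturation_sd * ref_sd) "kept" else "stopped"
    }
    trace[[step]] <- data.frame(step = step, candidate = cand,
                                mean_f1 = full$mean, sd_f1 = full$sd,
                                decision = decision, stringsAsFactors = FALSE)
    if (decision == "stopped") break
    selected <- c(selected, cand)
    pool <- setdiff(pool, cand)
    current <- full
  }
  if (!is.null(trace[[length(trace)]]) &&
      trace[[length(trace)]]$decision == "kept" &&
      (length(pool) == 0 || length(selected) >= max_features)) {
    trace[[length(trace)]]$decision <- "kept_exhausted"
  }
  list(features = selected, trace = do.call(rbind, trace),
       mean = current$mean, sd = current$sd, per_trial = current$per_trial)
}

#' Partial dependence of the classifier on one feature
#'
#' For every grid value g, sets the feature to g in every row of the data
#' and averages the predicted positive-class probability.
#'
#' @param model An [fit_boost()] model.
#' @param features Data the dependence is marginalized over.
#' @param feature_name Feature to vary.
#' @param grid Grid values (default: up to `grid_size` unique values or
#'   quantiles of the feature).
#' @param grid_size Default grid resolution (20).
#' @return Data frame with `value` and `mean_probability`.
#' @export
partial_dependence <- function(model, features, feature_name, grid = NULL,
                               grid_size = 20L) {
  df <- as.data.frame(features)
  if (!feature_name %in% names(df)) {
    stop(sprintf("unknown feature '%s'", feature_name), call. = FALSE)
  }
  if (is.null(grid)) {
    vals <- sort(unique(as.numeric(df[[feature_name]])))
    grid <- if (length(vals) <= grid_size) vals else {
      unname(stats::quantile(as.numeric(df[[feature_name]]),
                             probs = seq(0, 1, length.out = grid_size),
                             type = 7))
    }
  }
  mp <- vapply(grid, function(g) {
    df[[feature_name]] <- g
    mean(predict_prob(model, df))
  }, numeric(1))
  data.frame(value = grid, mean_probability = mp)
}

# Recompute a derived (product/quotient) column from clamped parent values
# using its provenance record.
.derived_value <- function(prov_record, a_val, b_val) {
  if (prov_record$type == "product") return(a_val * b_val)
  rs <- prov_record$ranges
  sc <- function(v, r) if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else 0
  sc(a_val, rs[[1]]) / (sc(b_val, rs[[2]]) + 1e-6)
}

# Interaction surface for a derived feature: clamp the parents on a grid,
# recompute the derived column, and average the predicted probabilities
# over the remaining columns of `df`.
.derived_interaction_surface <- function(model, df, feature, prov_record,
                                         grid_size = 10L) {
  parents <- prov_record$parents
  default_grid <- function(f) {
    vals <- sort(unique(as.numeric(df[[f]])))
    if (length(vals) <= grid_size) vals else {
      unname(stats::quantile(as.numeric(df[[f]]),
                             probs = seq(0, 1, length.out = grid_size),
                             type = 7))
    }
  }
  ga <- default_grid(parents[1])
  gb <- default_grid(parents[2])
  out <- matrix(NA_real_, length(ga), length(gb),
                dimnames = list(format(ga), format(gb)))
  for (i in seq_along(ga)) {
    for (j in seq_along(gb)) {
      df2 <- df
      df2[[parents[1]]] <- ga[i]
      df2[[parents[2]]] <- gb[j]
      df2[[feature]] <- .derived_value(prov_record, ga[i], gb[j])
      out[i, j] <- mean(predict_prob(model, df2))
    }
  }
  attr(out, "parents") <- parents
  out
}

#' Joint partial-dependence surface for a feature pair
#'
#' Grid x grid matrix of average predicted positive-class probabilities with
#' both features clamped; the data product behind two-way interaction
#' heatmaps.
#'
#' @param model An [fit_boost()] model.
#' @param features Data the surface is marginalized over.
#' @param feature_pair Character vector of two feature names.
#' @param grids Optional list of two grid vectors.
#' @param grid_size Default per-axis grid resolution (10).
#' @return Numeric matrix (rows: first feature grid, columns: second) with
#'   `dimnames` set to the grid values.
#' @export
interaction_heatmap <- function(model, features, feature_pair, grids = NULL,
                                grid_size = 10L) {
  stopifnot(length(feature_pair) == 2)
  df <- as.data.frame(features)
  for (f in feature_pair) {
    if (!f %in% names(df)) stop(sprintf("unknown feature '%s'", f), call. = FALSE)
  }
  default_grid <- function(f) {
    vals <- sort(unique(as.numeric(df[[f]])))
    if (length(vals) <= grid_size) vals else {
      unname(stats::quantile(as.numeric(df[[f]]),
                             probs = seq(0, 1, length.out = grid_size),
                             type = 7))
    }
  }
  if (is.null(grids)) grids <- lapply(feature_pair, default_grid)
  out <- matrix(NA_real_, length(grids[[1]]), length(grids[[2]]),
                dimnames = list(format(grids[[1]]), format(grids[[2]])))
  for (i in seq_along(grids[[1]])) {
    for (j in seq_along(grids[[2]])) {
      df2 <- df
      df2[[feature_pair[1]]] <- grids[[1]][i]
      df2[[feature_pair[2]]] <- grids[[2]][j]
      out[i, j] <- mean(predict_prob(model, df2))
    }
  }
  out
}
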