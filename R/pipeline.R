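# End-to-end orchestration: simulate -> score -> cluster -> profile ->
# compare -> classify, with validation, reproducibility metadata and
# plain-text artifacts (CSV/JSON).

#' Default classifier feature columns of a synthetic cohort
#'
#' The explanatory feature inventory used by the classification stage:
#' demographics, HIV treatment indices, functional status, medical history
#' and symptom flags, medication flags, cognitive/motor raw scores, CTQ
#' item-level responses and CES-D positive-affect items. The three
#' phenotype-defining instruments (PHQ-9, BAI, PCL-C) are excluded.
#'
#' @return Character vector of column names.
#' @export
default_classifier_features <- function() {
  c("age", "sex", "education_years", "marital_status",
    "art_duration_months", "karnofsky",
    "sensory_symptoms", "balance_difficulty", "fit_seizure", "smoke",
    "hypertension", "diabetes", "med_niazid", "med_dapsone", "med_flagyl",
    "med_antihypertensive",
    "avlt_total_learning", "avlt_delayed_recall", "avlt_recognition",
    "pegs_dominant", "pegs_nondominant", "color_trails1_time",
    "color_trails2_time", "symbol_digit", "timed_gait",
    "color_trails1_near_misses", "color_trails2_near_misses",
    paste0("ctq_pa_item", 1:5), paste0("ctq_sa_item", 1:5),
    paste0("cesd_pa_item", 1:4))
}

# Encode a cohort column as numeric for the booster.
.encode_feature <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.logical(x)) return(as.numeric(x))
  if (all(x %in% c("male", "female"))) return(as.numeric(x == "male"))
  if (all(x %in% c("married", "not_married"))) return(as.numeric(x == "married"))
  as.numeric(factor(x))
}

#' Classify one phenotype against another
#'
#' The classification stage: restricts the cohort to two phenotypes
#' (defaults: PTSD vs minimal symptom), encodes the explanatory features,
#' removes constant columns, prunes redundancy (|r| > `r_threshold` groups
#' resolved by MIC against the class label), optionally appends two-way
#' interaction features among the strongest base features, runs greedy
#' forward selection under the 1-SD saturation rule with repeated
#' cross-validated F1, and fits the final model with partial-dependence and
#' interaction-surface exports.
#'
#' @param cohort Cohort data frame.
#' @param phenotype Per-row phenotype names (e.g. from
#'   [phenotype_clustering()]'s `phenotype` element).
#' @param classes Length-2 character: (positive class, reference class).
#' @param feature_cols Feature columns (default
#'   [default_classifier_features()] intersected with the cohort).
#' @param interactions `"none"` or `"two_way"`.
#' @param interaction_pool Number of top base features (by MIC with the
#'   label) interactions are built among (default 8).
#' @param r_threshold Redundancy threshold (default 0.65).
#' @param max_features,saturation_sd,config,folds,repeats,screen_repeats,base
#'   Passed to [select_features()] / [boost_config()].
#' @param seed Integer seed.
#' @return Object of class `classifier_report`: list with `classes`,
#'   `interactions`, `features`, `trace`, `mean_f1`, `sd_f1`, `per_trial`,
#'   `pdp` (named list of data frames), `heatmaps` (named list of matrices),
#'   `provenance`, `n`.
#' @export
classify_phenotypes <- function(cohort, phenotype,
                                classes = c("PTSD", "minimal_symptom"),
                                feature_cols = NULL,
                                interactions = c("none", "two_way"),
                                interaction_pool = 8L,
                                r_threshold = 0.65,
                                max_features = 10L, saturation_sd = 1.0,
                                config = boost_config(), folds = 5L,
                                repeats = 5L, screen_repeats = 1L,
                                base = "current", seed = 1L) {
  interactions <- match.arg(interactions)
  stopifnot(length(classes) == 2, nrow(cohort) == length(phenotype))
  sel <- phenotype %in% classes
  if (sum(phenotype == classes[1]) < folds || sum(phenotype == classes[2]) < folds) {
    stop("too few members of a class for stratified cross-validation",
         call. = FALSE)
  }
  dat <- cohort[sel, , drop = FALSE]
  y <- factor(phenotype[sel], levels = rev(classes))  # positive = classes[1]
  if (is.null(feature_cols)) {
    feature_cols <- intersect(default_classifier_features(), names(cohort))
  }
  enc <- as.data.frame(lapply(dat[, feature_cols, drop = FALSE], .encode_feature))
  fm <- drop_zero_variance(feature_matrix(enc))
  fm <- dedupe_features(fm, target = y, r_threshold = r_threshold)
  full_df <- as.data.frame(fm)
  full_prov <- provenance(fm)
  if (interactions == "two_way") {
    nms <- names(fm)
    if (length(nms) > interaction_pool) {
      mics <- vapply(nms, function(nm) {
        suppressWarnings(mic(as.numeric(fm[[nm]]), as.numeric(y)))
      }, numeric(1))
      top <- nms[order(-mics, nms)][seq_len(interaction_pool)]
    } else top <- nms
    inter <- build_interactions(.fm_subset(fm, top), "two_way",
                                r_threshold = r_threshold)
    rest <- setdiff(nms, top)
    merged <- cbind(as.data.frame(inter),
                    as.data.frame(fm)[, rest, drop = FALSE])
    prov <- c(provenance(inter),
              provenance(fm)[rest])
    full_df <- merged
    full_prov <- prov
    fm <- dedupe_features(feature_matrix(merged, prov), target = y,
                          r_threshold = r_threshold)
  }
  selres <- select_features(fm, y, max_features = max_features,
                            saturation_sd = saturation_sd, config = config,
                            folds = folds, repeats = repeats,
                            screen_repeats = screen_repeats, base = base,
                            seed = seed, positive = classes[1])
  final_fm <- as.data.frame(fm)[, selres$features, drop = FALSE]
  model <- fit_boost(final_fm, y, config, positive = classes[1], seed = seed)
  pdp <- stats::setNames(lapply(selres$features, function(f) {
    partial_dependence(model, final_fm, f)
  }), selres$features)
  prov_all <- provenance(fm)
  inter_feats <- selres$features[vapply(selres$features, function(f) {
    prov_all[[f]]$type %in% c("product", "quotient")
  }, logical(1))]
  heatmaps <- stats::setNames(lapply(inter_feats, function(f) {
    .derived_interaction_surface(model, full_df, f, full_prov[[f]])
  }), inter_feats)
  structure(list(classes = classes, interactions = interactions,
                 features = selres$features, trace = selres$trace,
                 mean_f1 = selres$mean, sd_f1 = selres$sd,
                 per_trial = selres$per_trial, pdp = pdp,
                 heatmaps = heatmaps,
                 provenance = prov_all[selres$features],
                 model = model, n = nrow(dat), seed = seed),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s vs %s (n = %d), interactions = %s\n",
              x$classes[1], x$classes[2], x$n, x$interactions))
  cat(sprintf("  mean F1 = %.3f (SD %.3f) over %d trials\n", x$mean_f1,
              x$sd_f1, length(x$per_trial)))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Validate a cohort table against a schema
#'
#' Checks required columns, types and ranges; never mutates the data.
#'
#' @param table Data frame to validate.
#' @param schema List of column specs: each a list with `name`, optional
#'   `type` (`"numeric"`, `"integer"`, `"binary"`, `"categorical"`),
#'   optional `min`/`max`, optional `values`, optional `required`
#'   (default `TRUE`).
#' @return Data frame of violations with `row`, `column`, `issue`
#'   (zero rows when the table is clean).
#' @export
validate_inputs <- function(table, schema) {
  violations <- list()
  add <- function(row, column, issue) {
    violations[[length(violations) + 1L]] <<- data.frame(
      row = row, column = column, issue = issue, stringsAsFactors = FALSE)
  }
  for (spec in schema) {
    nm <- spec$name
    required <- !isFALSE(spec$required)
    if (!nm %in% names(table)) {
      if (required) add(NA_integer_, nm, "missing required column")
      next
    }
    x <- table[[nm]]
    miss <- which(is.na(x))
    for (r in miss) add(r, nm, "missing value")
    obs <- which(!is.na(x))
    if (!is.null(spec$type) && spec$type %in% c("numeric", "integer", "binary")) {
      if (!is.numeric(x) && !is.logical(x)) {
        add(NA_integer_, nm, sprintf("expected %s column", spec$type))
        next
      }
      if (spec$type == "integer") {
        bad <- obs[x[obs] != floor(x[obs])]
        for (r in bad) add(r, nm, "non-integer value")
      }
      if (spec$type == "binary") {
        bad <- obs[!x[obs] %in% c(0, 1)]
        for (r in bad) add(r, nm, "not in {0, 1}")
      }
    }
    if (!is.null(spec$min)) {
      bad <- obs[x[obs] < spec$min]
      for (r in bad) add(r, nm, sprintf("below minimum %s", format(spec$min)))
    }
    if (!is.null(spec$max)) {
      bad <- obs[x[obs] > spec$max]
      for (r in bad) add(r, nm, sprintf("above maximum %s", format(spec$max)))
    }
    if (!is.null(spec$values)) {
      bad <- obs[!x[obs] %in% spec$values]
      for (r in bad) add(r, nm, "value outside allowed set")
    }
  }
  out <- if (length(violations) > 0) do.call(rbind, violations) else {
    data.frame(row = integer(0), column = character(0), issue = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Default item-response schema for cohort validation
#'
#' One spec per instrument item column with the instrument's range.
#'
#' @return Schema list for [validate_inputs()].
#' @export
default_cohort_schema <- function() {
  schema <- list()
  for (ins in instrument_names()) {
    spec <- instrument_spec(ins)
    prefix <- .instrument_prefixes()[[ins]]
    for (item in seq_len(spec$n_items)) {
      schema[[length(schema) + 1L]] <- list(
        name = paste0(prefix, "_item", item), type = "integer",
        min = spec$item_min, max = spec$item_max)
    }
  }
  schema
}

#' Pipeline run configuration
#'
#' @param out_dir Output directory for stage artifacts.
#' @param seed Global seed; every stochastic stage derives from it.
#' @param stages Stages to run, in pipeline order; subset of
#'   `c("simulate", "score", "cluster", "profile", "compare", "classify")`.
#' @param cohort_csv Optional path to an existing cohort CSV (used when
#'   `"simulate"` is not run).
#' @param cohort A [cohort_config()] for the simulate stage.
#' @param embedding An [embedding_config()] (its seed is overridden by
#'   the global seed).
#' @param classifier_interactions `"none"`, `"two_way"`, or `"both"`.
#' @param classifier_max_features Feature cap for the selection stage
#'   (default 10).
#' @param boost A [boost_config()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("mhpheno_run_"), seed = 1L,
                       stages = c("simulate", "score", "cluster", "profile",
                                  "compare", "classify"),
                       cohort_csv = NULL,
                       cohort = cohort_config(seed = seed),
                       embedding = embedding_config(),
                       classifier_interactions = "none",
                       classifier_max_features = 10L,
                       boost = boost_config()) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!"simulate" %in% stages && is.null(cohort_csv) &&
      any(c("score", "cluster", "profile", "compare", "classify") %in% stages)) {
    stop("need cohort_csv when the simulate stage is disabled", call. = FALSE)
  }
  embedding$seed <- as.integer(seed)
  cohort$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 cohort_csv = cohort_csv, cohort = cohort,
                 embedding = embedding,
                 classifier_interactions = classifier_interactions,
                 classifier_max_features = as.integer(classifier_max_features),
                 boost = boost),
            class = "run_config")
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the phenotyping pipeline end-to-end
#'
#' Executes the enabled stages in order (simulate, score, cluster, profile,
#' compare, classify), writing one or more plain-text artifacts per stage
#' into `config$out_dir`, and returns a manifest listing artifacts, seeds
#' and checksums. A stage failure halts downstream stages with an error.
#'
#' @param config A [run_config()].
#' @return Manifest list (also written to `manifest.json`): package version,
#'   seed, per-stage artifact paths, row counts and MD5 checksums.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "mhpheno",
                   version = as.character(utils::packageVersion("mhpheno")),
                   seed = config$seed, stages = list())
  artifacts <- character(0)
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }

  cohort <- NULL
  if ("simulate" %in% config$stages) {
    cohort <- generate_cohort(config$cohort, seed = config$seed)
    path <- .write_csv(cohort, file.path(config$out_dir, "cohort.csv"))
    truth <- list(seed = config$seed,
                  latent_phenotype = stats::setNames(
                    as.list(cohort$latent_phenotype), cohort$id),
                  planted_effects = attr(cohort, "planted_effects"))
    truth_path <- file.path(config$out_dir, "cohort_truth.json")
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, pretty = TRUE)
    manifest$stages$simulate <- list(artifacts = c(path, truth_path),
                                     n = nrow(cohort))
    artifacts <- c(artifacts, path, truth_path)
    log_stage("simulate", sprintf("%d participants", nrow(cohort)))
  } else if (!is.null(config$cohort_csv)) {
    cohort <- utils::read.csv(config$cohort_csv, stringsAsFactors = FALSE)
    log_stage("load", sprintf("%d participants from %s", nrow(cohort),
                              config$cohort_csv))
  }

  scored <- NULL
  if ("score" %in% config$stages) {
    issues <- validate_inputs(cohort, default_cohort_schema())
    if (nrow(issues) > 0) {
      stop(sprintf("input validation failed with %d violation(s); first: %s/%s",
                   nrow(issues), issues$column[1], issues$issue[1]),
           call. = FALSE)
    }
    scored <- score_cohort(cohort)
    path <- .write_csv(scored, file.path(config$out_dir, "scored.csv"))
    manifest$stages$score <- list(artifacts = path, n = nrow(scored))
    artifacts <- c(artifacts, path)
    log_stage("score", sprintf("%d participants scored", nrow(scored)))
  }

  solution <- NULL
  if ("cluster" %in% config$stages) {
    solution <- phenotype_clustering(scored, embed_config = config$embedding)
    assign_df <- data.frame(id = scored$id, cluster = solution$labels,
                            phenotype = solution$phenotype,
                            solution$embedding)
    path <- .write_csv(assign_df, file.path(config$out_dir, "assignments.csv"))
    summ <- list(seed = config$seed,
                 cluster_sizes = as.list(solution$cluster_sizes),
                 silhouette = solution$silhouette,
                 phenotypes = as.list(solution$phenotypes),
                 summaries = solution$summaries)
    summ_path <- file.path(config$out_dir, "cluster_summary.json")
    jsonlite::write_json(summ, summ_path, auto_unbox = TRUE, pretty = TRUE,
                         dataframe = "rows", digits = NA)
    manifest$stages$cluster <- list(
      artifacts = c(path, summ_path),
      n_clusters = sum(names(solution$cluster_sizes) != "noise"),
      n_noise = sum(solution$labels == 0),
      silhouette = solution$silhouette)
    artifacts <- c(artifacts, path, summ_path)
    log_stage("cluster", sprintf("%d clusters, %d noise, silhouette %.3f",
                                 sum(names(solution$cluster_sizes) != "noise"),
                                 sum(solution$labels == 0),
                                 solution$silhouette))
  }

  if ("profile" %in% config$stages) {
    prof <- profile_items(scored, solution$labels)
    strip <- export_strip_data(scored, solution$labels)
    p1 <- .write_csv(prof, file.path(config$out_dir, "item_profiles.csv"))
    p2 <- .write_csv(strip, file.path(config$out_dir, "strip_data.csv"))
    manifest$stages$profile <- list(artifacts = c(p1, p2),
                                    n_profiles = nrow(prof))
    artifacts <- c(artifacts, p1, p2)
    log_stage("profile", sprintf("%d profile rows", nrow(prof)))
  }

  if ("compare" %in% config$stages) {
    ph <- solution$phenotype
    ref_cluster <- names(which(solution$phenotypes == "minimal_symptom"))[1]
    comp <- compare_to_referent(scored, solution$labels,
                                referent = as.integer(ref_cluster))
    path <- .write_csv(comp, file.path(config$out_dir, "comparisons.csv"))
    manifest$stages$compare <- list(artifacts = path, referent = ref_cluster,
                                    n_tests = nrow(comp))
    artifacts <- c(artifacts, path)
    log_stage("compare", sprintf("%d tests vs referent cluster %s",
                                 nrow(comp), ref_cluster))
  }

  if ("classify" %in% config$stages) {
    modes <- switch(config$classifier_interactions,
                    both = c("none", "two_way"),
                    config$classifier_interactions)
    for (mode in modes) {
      rep <- classify_phenotypes(scored, solution$phenotype,
                                 interactions = mode, config = config$boost,
                                 max_features = config$classifier_max_features,
                                 seed = config$seed)
      tag <- if (mode == "two_way") "with_interactions" else "no_interactions"
      rep_path <- file.path(config$out_dir,
                            sprintf("classifier_%s.json", tag))
      jsonlite::write_json(
        list(classes = rep$classes, interactions = rep$interactions,
             features = rep$features, mean_f1 = rep$mean_f1,
             sd_f1 = rep$sd_f1, per_trial = rep$per_trial,
             trace = rep$trace, seed = config$seed),
        rep_path, auto_unbox = TRUE, pretty = TRUE, dataframe = "rows",
        digits = NA)
      pdp_df <- do.call(rbind, lapply(names(rep$pdp), function(f) {
        cbind(feature = f, rep$pdp[[f]])
      }))
      pdp_path <- .write_csv(pdp_df, file.path(
        config$out_dir, sprintf("classifier_%s_pdp.csv", tag)))
      manifest$stages[[paste0("classify_", tag)]] <- list(
        artifacts = c(rep_path, pdp_path), mean_f1 = rep$mean_f1,
        sd_f1 = rep$sd_f1, n_features = length(rep$features))
      artifacts <- c(artifacts, rep_path, pdp_path)
      log_stage("classify", sprintf("%s: F1 %.3f (SD %.3f), %d features",
                                    tag, rep$mean_f1, rep$sd_f1,
                                    length(rep$features)))
    }
  }

  manifest$checksums <- as.list(tools::md5sum(artifacts))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, dataframe = "rows",
                       digits = NA)
  invisible(manifest)
}
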