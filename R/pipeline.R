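#' Pipeline run configuration
#'
#' Assembles the configuration for a full simulate - extract - fit -
#' score - compare run. One seed governs every stochastic stage through
#' derived substreams.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed.
#' @param mode `"features"` (simulate at the analysis-variable level) or
#'   `"landmarks"` (simulate 3D landmark cohorts, build meshes, extract
#'   the 52 distances and facial area).
#' @param cohort generator configuration: a [feature_table_config()] or
#'   [cohort_config()] matching `mode` (defaults constructed per mode).
#' @param k_folds cross-validation folds (default 10).
#' @param max_features maximum features selected for the gender model.
#' @param covariates candidate covariates screened before the ANCOVA.
#' @param familywise_rate familywise alpha (default 0.05).
#' @param family_size Bonferroni family size (default 10, the facial
#'   distances).
#' @param diagnosis_features predictor set for the diagnosis classifier;
#'   `NULL` selects the masculinity score plus the significantly different
#'   distances.
#' @param mesh_resolution,edge_points geometry settings for landmark mode.
#' @param features_file,meta_file optional paths to existing feature and
#'   metadata CSVs; when given, the simulate stage is skipped and the
#'   extract stage reads these files instead.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("facemasc_run_"), seed = 1L,
                       mode = c("features", "landmarks"), cohort = NULL,
                       k_folds = 10L, max_features = 10L,
                       covariates = c("facial_area", "age"),
                       familywise_rate = 0.05, family_size = 10L,
                       diagnosis_features = NULL,
                       mesh_resolution = 7, edge_points = 3L,
                       features_file = NULL, meta_file = NULL) {
  mode <- match.arg(mode)
  cohort <- cohort %||% switch(mode,
                               features = feature_table_config(),
                               landmarks = cohort_config(seed = derive_seed(seed, 1L)))
  structure(list(out_dir = out_dir, seed = as.integer(seed), mode = mode,
                 cohort = cohort, k_folds = as.integer(k_folds),
                 max_features = as.integer(max_features),
                 covariates = covariates,
                 familywise_rate = familywise_rate,
                 family_size = as.integer(family_size),
                 diagnosis_features = diagnosis_features,
                 mesh_resolution = mesh_resolution,
                 edge_points = as.integer(edge_points),
                 features_file = features_file, meta_file = meta_file),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a YAML mapping whose keys are [run_config()] arguments (e.g.
#' `seed`, `mode`, `out_dir`, `k_folds`, `family_size`,
#' `diagnosis_features`, `features_file`, `meta_file`) and builds the run
#' configuration; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stopf("config file '%s' must be a YAML mapping", path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) stopf("unknown config key(s): %s",
                              paste(bad, collapse = ", "))
  if (!is.null(raw$covariates)) raw$covariates <- unlist(raw$covariates)
  if (!is.null(raw$diagnosis_features)) {
    raw$diagnosis_features <- unlist(raw$diagnosis_features)
  }
  do.call(run_config, raw)
}

config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  x$cohort <- unclass(x$cohort)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes simulate, extract, fit, score and compare in order, writing
#' each stage's output under `config$out_dir` (metadata, features, model
#' JSON, scores, comparison table, density grid, run report JSON) and
#' returning the run report. Rerunning with the same configuration and
#' seed reproduces the report exactly.
#'
#' @param config a [run_config()].
#' @return The run report (list), invisibly also written to
#'   `report.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  n_warn <- 0L
  report <- withCallingHandlers(
    run_pipeline_stages(config),
    warning = function(w) {
      n_warn <<- n_warn + 1L
      invokeRestart("muffleWarning")
    })
  report$n_warnings <- n_warn
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

run_pipeline_stages <- function(config) {
  out <- config$out_dir
  seed <- config$seed

  ## simulate / extract from files ------------------------------------------
  if (!is.null(config$features_file) || !is.null(config$meta_file)) {
    for (f in c(config$features_file, config$meta_file)) {
      if (!file.exists(f)) {
        stopf("extract stage: input file not found: %s", f)
      }
    }
    meta <- read_metadata(config$meta_file)
    features <- read.csv(config$features_file, stringsAsFactors = FALSE)
    if (!"subject_id" %in% names(features)) {
      stopf("extract stage: features file lacks a subject_id column")
    }
  } else if (config$mode == "features") {
    tab <- generate_feature_table(config$cohort, seed = derive_seed(seed, 1L))
    meta <- tab[, c("subject_id", "sex", "family_group", "age")]
    features <- tab[, setdiff(names(tab), c("sex", "family_group", "age",
                                            "masculinity_score"))]
    features <- cbind(features,
                      tab[, "masculinity_score", drop = FALSE])
    names(features)[names(features) == "masculinity_score"] <- "reference_score"
  } else {
    cohort <- config$cohort
    cohort$seed <- derive_seed(seed, 1L)
    sim <- generate_cohort(cohort, meshes = FALSE)
    meta <- sim$subjects
    write_landmarks(sim$landmarks, file.path(out, "landmarks.csv"))
    template <- fixture_mesh("face_template",
                             resolution = config$mesh_resolution)
    features <- extract_feature_table(sim$landmarks, meshes = TRUE,
                                      template = template,
                                      edge_points = config$edge_points)
  }
  write_metadata(meta, file.path(out, "meta.csv"))
  write.csv(features, file.path(out, "features.csv"), row.names = FALSE,
            quote = FALSE)

  ## transform --------------------------------------------------------------
  analysis <- transform_features(merge(meta, features, by = "subject_id",
                                       sort = FALSE),
                                 audit_skewness = FALSE)

  ## fit + score ------------------------------------------------------------
  dist_cols <- grep("^(e|g)_", names(analysis), value = TRUE)
  model <- fit_gender_model(analysis[, dist_cols, drop = FALSE],
                            analysis$sex,
                            max_features = config$max_features,
                            k = config$k_folds, seed = derive_seed(seed, 2L))
  write_gender_model(model, file.path(out, "model.json"))
  scores <- masculinity_score(model, analysis)
  write.csv(scores, file.path(out, "scores.csv"), row.names = FALSE,
            quote = FALSE)
  analysis$masculinity_score <- scores$score

  ## compare ----------------------------------------------------------------
  analysis_vars <- c("masculinity_score", intersect(
    c("e_nose_width", "e_nasal_tip_protrusion", "e_nasal_bridge_length",
      "e_upper_lip_height", "g_upper_facial_height", "g_outer_canthal_width",
      "g_forehead_width", "g_mandible_height", "g_upper_cheek_height_left",
      "g_upper_cheek_height_right"), names(analysis)))
  screen <- screen_covariates(analysis, analysis_vars,
                              covariates = config$covariates)
  used_cov <- unique(screen$covariate[screen$include])
  comparisons <- group_comparison_table(analysis, analysis_vars,
                                        covariates = used_cov,
                                        familywise_rate = config$familywise_rate,
                                        family_size = config$family_size)
  write.csv(comparisons, file.path(out, "results.csv"), row.names = FALSE)

  diag_feats <- config$diagnosis_features %||% unique(c(
    "masculinity_score",
    comparisons$variable[comparisons$significant &
                           comparisons$variable != "masculinity_score"]))
  # the score is a linear combination of the model's selected distances;
  # if the predictor set contains all of them, drop the least significant
  # to keep the within-class covariance full rank
  if (all(model$selected_features %in% diag_feats)) {
    cand <- comparisons[comparisons$variable %in% model$selected_features, ]
    drop_var <- cand$variable[which.max(cand$p_group)]
    diag_feats <- setdiff(diag_feats, drop_var)
    message(sprintf("diagnosis stage: dropping '%s' (collinear with the score)",
                    drop_var))
  }
  diag_acc <- classify_diagnosis(analysis, diag_feats, k = config$k_folds,
                                 seed = derive_seed(seed, 3L))

  dens <- density_report(analysis$masculinity_score,
                         analysis[, c("sex", "family_group")])
  dens_df <- data.frame(score = dens$grid,
                        lapply(dens$cells, function(cl) cl$density),
                        check.names = FALSE)
  write.csv(dens_df, file.path(out, "density.csv"), row.names = FALSE)

  list(
    config_hash = config_hash(config),
    seed = config$seed,
    mode = config$mode,
    n_subjects = nrow(analysis),
    selected_features = model$selected_features,
    gender_cv_accuracy = model$cv_accuracy,
    score_clipped = attr(scores, "n_clipped"),
    covariates_used = used_cov,
    covariate_screen = screen,
    comparisons = comparisons,
    per_test_alpha = bonferroni_alpha(config$family_size,
                                      config$familywise_rate),
    diagnosis_features = diag_feats,
    diagnosis_cv_accuracy = diag_acc)
}
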