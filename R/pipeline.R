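#' Default end-to-end pipeline configuration
#'
#' The default run simulates the emulated 23-therapist x 2-client design,
#' preprocesses (Z-scoring, -0.5/+0.5 coding, KNN imputation of income),
#' derives and standardizes the five client-level targets, and searches
#' all five model families over the full study predictor set (16
#' predictors: 146 candidate terms, traversed by the beam search).
#'
#' @param seed integer seed for the simulated study.
#' @param outcomes which of the five model families to run.
#' @param max_terms,drop_threshold,cv_pool_size,beam_width,budget search
#'   settings, see [select_model()].
#' @param knn_k neighbours for income imputation.
#' @param predictors optional predictor declaration data.frame overriding
#'   the full 16-predictor study universe (columns `name`, `type`, `level`).
#' @param simulate a list of [synthetic_config()] overrides, or `NULL` to
#'   read CSV inputs from `paths` instead.
#' @param paths list with `therapists`, `clients`, `sessions` CSV paths
#'   (only when `simulate` is `NULL`).
#' @return A configuration list for [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L,
                            outcomes = c("outcome_slope",
                                         "alliance_between_client",
                                         "alliance_between_therapist",
                                         "alliance_within_client",
                                         "alliance_within_therapist"),
                            max_terms = 9, drop_threshold = 0.10,
                            cv_pool_size = 50, beam_width = 100,
                            budget = 2e6, knn_k = 5, predictors = NULL,
                            simulate = list(), paths = NULL) {
  list(seed = as.integer(seed), outcomes = outcomes, max_terms = max_terms,
       drop_threshold = drop_threshold, cv_pool_size = cv_pool_size,
       beam_width = beam_width, budget = budget, knn_k = knn_k,
       predictors = predictors, simulate = simulate, paths = paths)
}

#' Study predictor declarations used by the default pipeline universe
#'
#' The 16 baseline predictors of the emulated study: client and therapist
#' demographics (gender, age, income), therapist characteristics (FIS
#' level, clinical training, orientation) and client characteristics
#' (SSI, IIP, baseline OQ-45 total and its three subscales, prior
#' treatment). Yields a 146-term universe (16 linear + 10 quadratic +
#' 120 interactions).
#'
#' @return data.frame with columns `name`, `type`, `level` for
#'   [build_universe()].
#' @export
default_predictors <- function() {
  data.frame(
    name = c("therapist_age", "therapist_gender", "therapist_income",
             "fis_level", "training", "orientation",
             "age", "gender", "income", "ssi_total", "iip_total",
             "oq_total_baseline", "oq_sub_symptom", "oq_sub_interpersonal",
             "oq_sub_social_role", "prior_treatment"),
    type = c("continuous", "binary", "continuous", "binary", "binary",
             "binary", "continuous", "binary", "continuous", "continuous",
             "continuous", "continuous", "continuous", "continuous",
             "continuous", "binary"),
    level = c(rep("therapist", 6), rep("client", 10)),
    stringsAsFactors = FALSE)
}

#' Default -0.5/+0.5 codings for the study's binary predictors
#' @return named list for [code_binaries()].
#' @export
default_binary_codings <- function() {
  list(`therapists.gender` = c(female = -0.5, male = 0.5),
       fis_level = c(low = -0.5, high = 0.5),
       training = c(untrained = -0.5, trained = 0.5),
       orientation = c(eclectic_undetected = -0.5, cog_dyn_hum = 0.5),
       `clients.gender` = c(female = -0.5, male = 0.5),
       prior_treatment = c(no = -0.5, yes = 0.5))
}

#' Preprocess a dyadic study dataset for modelling
#'
#' Standardizes all continuous baseline predictors (sample mean/sd),
#' recodes binary predictors to -0.5/+0.5, and imputes missing client
#' income by k-nearest neighbours over the standardized client predictor
#' matrix.
#'
#' @param x a `dyad_dataset`.
#' @param knn_k neighbours for imputation (default 5).
#' @return A list: `dataset` (preprocessed), `scaling` (stats used).
#' @export
preprocess_study <- function(x, knn_k = 5) {
  cont_th <- c("therapists.age", "therapists.income")
  cont_cl <- c("clients.age", "clients.income", "ssi_total", "iip_total",
               "oq_total_baseline", "oq_sub_symptom", "oq_sub_interpersonal",
               "oq_sub_social_role")
  z <- zscore_continuous(x, c(cont_th, cont_cl))
  ds <- code_binaries(z$dataset, default_binary_codings())
  cl_mat <- as.matrix(ds$clients[, c("age", "gender", "income", "ssi_total",
                                     "iip_total", "oq_total_baseline",
                                     "oq_sub_symptom", "oq_sub_interpersonal",
                                     "oq_sub_social_role", "prior_treatment")])
  if (anyNA(cl_mat)) {
    imp <- knn_impute(cl_mat, k = knn_k)
    for (nm in colnames(cl_mat)) ds$clients[[nm]] <- imp[, nm]
    ds$provenance$imputation <- attr(imp, "imputation_log")
  }
  list(dataset = ds, scaling = z$stats)
}

#' Run the full five-model pipeline
#'
#' simulate/read -> preprocess -> derive targets -> best-subset search per
#' outcome -> report. Artifacts written to `out_dir`: `targets.csv`,
#' per-outcome `report_<outcome>.txt` / `.json` and
#' `search_ledger_<outcome>.csv`, effect grids for the selected quadratic
#' and interaction terms under `effect_grids/`, and `manifest.json`
#' recording seeds, settings and the selection notes. Reruns with an
#' identical configuration produce identical artifacts.
#'
#' @param config list from [pipeline_config()].
#' @param out_dir artifact directory (created if needed).
#' @return Invisibly, a list with the dataset, analysis table and the
#'   per-outcome search results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(seed = config$seed, settings = config[
    c("max_terms", "drop_threshold", "cv_pool_size", "beam_width",
      "budget", "knn_k")], stage = "start")

  if (!is.null(config$simulate)) {
    cfg <- do.call(synthetic_config,
                   modifyList(list(seed = config$seed), config$simulate))
    sim <- generate_study(cfg)
    ds <- sim$dataset
    manifest$input <- list(kind = "simulated", seed = config$seed,
                           n_therapists = cfg$n_therapists,
                           clients_per_therapist = cfg$clients_per_therapist)
  } else {
    ds <- read_study_tables(config$paths$therapists, config$paths$clients,
                            config$paths$sessions)
    manifest$input <- list(kind = "csv", paths = config$paths)
  }

  prep <- preprocess_study(ds, knn_k = config$knn_k)
  targets <- standardize_targets(derive_targets(prep$dataset))
  tab <- build_analysis_table(prep$dataset, targets)
  utils::write.csv(targets, file.path(out_dir, "targets.csv"),
                   row.names = FALSE)

  universe <- build_universe(
    if (is.null(config$predictors)) default_predictors() else config$predictors)
  results <- list()
  for (oc in config$outcomes) {
    dat <- tab[!is.na(tab[[oc]]), , drop = FALSE]
    sr <- select_model(dat, universe, oc,
                       max_terms = config$max_terms,
                       drop_threshold = config$drop_threshold,
                       cv_pool_size = config$cv_pool_size,
                       budget = config$budget,
                       beam_width = config$beam_width,
                       seed = config$seed)
    diag <- residual_diagnostics(sr$fit)
    bundle <- render_model_report(sr$fit, sr$cv, diag,
                                  meta = list(search_mode = sr$search_mode,
                                              seed = config$seed,
                                              drop_threshold = sr$drop_threshold,
                                              drop_mode = sr$drop_mode,
                                              selection_note = sr$selection_note))
    writeLines(format_report(bundle),
               file.path(out_dir, sprintf("report_%s.txt", oc)))
    report_to_json(bundle, file.path(out_dir, sprintf("report_%s.json", oc)))
    utils::write.csv(sr$ledger,
                     file.path(out_dir, sprintf("search_ledger_%s.csv", oc)),
                     row.names = FALSE)
    grid_dir <- file.path(out_dir, "effect_grids")
    if (!dir.exists(grid_dir)) dir.create(grid_dir)
    for (t in sr$selected$terms) {
      if (t$kind == "linear") next
      g <- effect_grid(sr$fit, t)
      utils::write.csv(as.data.frame(g),
                       file.path(grid_dir, sprintf("%s_%s.csv", oc,
                                                   gsub("[:^]", "_",
                                                        term_label(t)))),
                       row.names = FALSE)
    }
    results[[oc]] <- sr
    manifest$models[[oc]] <- list(selected = vapply(sr$selected$terms,
                                                    term_label, ""),
                                  aic = sr$fit$aic,
                                  r2_train = sr$fit$r2_marginal,
                                  r2_cv = sr$cv$r2_cv,
                                  search_mode = sr$search_mode,
                                  note = sr$selection_note)
  }
  manifest$stage <- "complete"
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dataset = prep$dataset, analysis_table = tab,
                 results = results, manifest = manifest))
}
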