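#' Resolved run configuration
#'
#' Collects every tunable of the pipeline in one object so a run is fully
#' described by (config, seed). The input is either a synthetic scenario or
#' a directory of ShanghaiT2DM-style participant files.
#'
#' @param input_mode `"synthetic"` or `"shanghai_dir"`.
#' @param n,scenario,days,meals_per_day_mean,sampling_min,missing_cgm_rate,missing_gram_rate
#'   Synthetic-cohort parameters (see [generate_cohort()]).
#' @param shanghai_dir Directory of per-participant files (`input_mode =
#'   "shanghai_dir"`).
#' @param window_min,anchor_tol_min,min_points,min_coverage_min Outcome
#'   labelling parameters (see [compute_iauc()]).
#' @param min_obs Eligibility threshold (see [apply_eligibility()]).
#' @param fast_grid Use [fast_hyper_grid()] instead of the full grid.
#' @param train_frac,k,threshold Modelling parameters.
#' @param seed Master seed for generation and fitting.
#' @return List of class `ppg_config`.
#' @export
ppg_config <- function(input_mode = c("synthetic", "shanghai_dir"),
                       n = 67, scenario = "mixed", days = 14,
                       meals_per_day_mean = 3.23, sampling_min = 15,
                       missing_cgm_rate = 0, missing_gram_rate = 0,
                       shanghai_dir = NULL,
                       window_min = 120, anchor_tol_min = 20,
                       min_points = 5, min_coverage_min = 100,
                       min_obs = 20,
                       fast_grid = FALSE, train_frac = 0.70, k = 4,
                       threshold = 0.5, seed = 1L) {
  structure(as.list(environment())[c(
    "input_mode", "n", "scenario", "days", "meals_per_day_mean",
    "sampling_min", "missing_cgm_rate", "missing_gram_rate", "shanghai_dir",
    "window_min", "anchor_tol_min", "min_points", "min_coverage_min",
    "min_obs", "fast_grid", "train_frac", "k", "threshold", "seed")],
    class = "ppg_config") -> cfg
  cfg$input_mode <- match.arg(input_mode)
  cfg
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys are [ppg_config()] arguments.
#' @return A `ppg_config`.
#' @export
ppg_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the yaml package")
  }
  do.call(ppg_config, yaml::read_yaml(path))
}

.stage <- function(stage, id, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed",
         if (!is.null(id)) paste0(" for participant ", id), ": ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes ingest/simulate -> label -> eligibility -> features -> fit (both
#' schemas) -> evaluate -> compare -> profile, and optionally writes the
#' standard artifact set (`observations.csv`, `exclusions.csv`,
#' `evaluation.csv`, `comparison.json`, `profiles.csv`,
#' `heterogeneity.csv`, `manifest.json`) into `out_dir`. Identical (config,
#' seed) gives identical outputs byte for byte.
#'
#' @param config A [ppg_config()].
#' @param out_dir Output directory; `NULL` skips writing.
#' @param cohort Optional pre-built list of [ppg_participant()] records,
#'   bypassing the config's input mode (used by the analysis drivers).
#' @param quiet Suppress per-stage progress messages.
#' @return List: `observations`, `eligibility`, `fits` (per participant,
#'   schema), `evaluation` (data frame), `comparison`
#'   (from [subgroup_and_test()]), `profiles` (gain), `shap_profiles`,
#'   `heterogeneity` (by best-model subgroup), `manifest`.
#' @export
run_pipeline <- function(config = ppg_config(), out_dir = NULL,
                         cohort = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  grid <- if (config$fast_grid) fast_hyper_grid() else default_hyper_grid()

  # --- ingest / simulate
  if (is.null(cohort)) {
    cohort <- .stage("ingest", NULL, switch(
      config$input_mode,
      synthetic = generate_cohort(
        config$n, config$scenario, seed = config$seed, days = config$days,
        meals_per_day_mean = config$meals_per_day_mean,
        sampling_min = config$sampling_min,
        missing_cgm_rate = config$missing_cgm_rate,
        missing_gram_rate = config$missing_gram_rate),
      shanghai_dir = {
        files <- list.files(config$shanghai_dir, "\\.(csv|xlsx?)$",
                            full.names = TRUE)
        if (!length(files)) stop("no participant files in ",
                                 config$shanghai_dir)
        lapply(files, read_shanghai_participant)
      }))
  }
  say("cohort: ", length(cohort), " participants")

  # --- label
  obs <- do.call(rbind, lapply(cohort, function(rec) {
    .stage("label", rec$participant_id,
           label_participant(rec, config$window_min, config$anchor_tol_min,
                             config$min_points, config$min_coverage_min))
  }))
  elig <- apply_eligibility(obs, config$min_obs)
  say("eligible: ", length(elig$included), " of ", length(cohort),
      " (", nrow(elig$exclusions), " excluded)")

  names(cohort) <- vapply(cohort, function(r) r$participant_id, character(1))

  # --- features + fits + per-schema evaluation
  fits <- list(); eval_rows <- list()
  for (id in elig$included) {
    rec <- cohort[[id]]
    pobs <- obs[obs$participant_id == id, , drop = FALSE]
    for (schema in c("low_burden", "high_burden")) {
      mat <- .stage("features", id,
                    assemble_matrix(rec, pobs, schema, config$train_frac))
      ft <- .stage("fit", id,
                   fit_participant(mat, grid = grid, k = config$k,
                                   seed = config$seed,
                                   threshold = config$threshold,
                                   train_frac = config$train_frac))
      fits[[paste(id, schema, sep = ".")]] <- ft
      sc <- score(ft$test_labels, ft$test_pred)
      eval_rows[[paste(id, schema, sep = ".")]] <- data.frame(
        participant_id = id, schema = schema,
        n_train = length(ft$train_idx), n_test = length(ft$test_idx),
        tp = sc$tp, fp = sc$fp, tn = sc$tn, fn = sc$fn,
        precision = sc$precision, recall = sc$recall, f1 = sc$f1,
        cv_f1 = ft$fit$mean_cv_f1, fallback = ft$fit$fallback)
    }
    say("fitted ", id)
  }
  evaluation <- do.call(rbind, c(eval_rows, make.row.names = FALSE))

  # --- compare
  comparison <- NULL; profiles <- list(); shap_profiles <- list()
  heterogeneity <- list()
  if (!is.null(evaluation) && nrow(evaluation)) {
    wide <- data.frame(
      participant_id = elig$included,
      f1_low = evaluation$f1[match(paste(elig$included, "low_burden"),
                                   paste(evaluation$participant_id,
                                         evaluation$schema))],
      f1_high = evaluation$f1[match(paste(elig$included, "high_burden"),
                                    paste(evaluation$participant_id,
                                          evaluation$schema))])
    comparison <- subgroup_and_test(wide)

    # --- profiles on each participant's best model
    for (i in seq_len(nrow(comparison$pairs))) {
      row <- comparison$pairs[i, ]
      if (row$best_schema == "incomparable") next
      schema <- if (row$best_schema == "tie") "low_burden" else row$best_schema
      ft <- fits[[paste(row$participant_id, schema, sep = ".")]]
      profiles[[row$participant_id]] <- gain_profile(ft)
      shap_profiles[[row$participant_id]] <- shap_profile(ft)
    }
    for (sg in c("low_better", "high_better")) {
      ids <- comparison$pairs$participant_id[comparison$pairs$subgroup == sg]
      ids <- intersect(ids, names(profiles))
      if (length(ids)) {
        heterogeneity[[sg]] <- cohort_heterogeneity(profiles[ids])
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ppgv")),
    config = unclass(config),
    n_input = length(cohort),
    n_included = length(elig$included),
    n_excluded = nrow(elig$exclusions),
    exclusion_reasons = as.list(table(elig$exclusions$reason)),
    n_observations = nrow(obs),
    n_usable = sum(obs$usable),
    subgroup_sizes = if (!is.null(comparison)) comparison$subgroup_sizes,
    outputs = c("observations.csv", "exclusions.csv", "evaluation.csv",
                "comparison.json", "profiles.csv", "heterogeneity.csv",
                "manifest.json"))

  result <- list(observations = obs, eligibility = elig, fits = fits,
                 evaluation = evaluation, comparison = comparison,
                 profiles = profiles, shap_profiles = shap_profiles,
                 heterogeneity = heterogeneity, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write the standard artifact set of a pipeline run
#'
#' @param result Return value of [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obs <- result$observations
  obs$meal_time <- .ts_format(obs$meal_time)
  utils::write.csv(obs, file.path(out_dir, "observations.csv"),
                   row.names = FALSE)
  utils::write.csv(result$eligibility$exclusions,
                   file.path(out_dir, "exclusions.csv"), row.names = FALSE)
  if (!is.null(result$evaluation)) {
    utils::write.csv(result$evaluation,
                     file.path(out_dir, "evaluation.csv"), row.names = FALSE)
  }
  if (!is.null(result$comparison)) {
    cm <- result$comparison
    jsonlite::write_json(
      list(subgroup_sizes = cm$subgroup_sizes, tests = cm$tests,
           best_f1_summary = cm$best_f1_summary, caveat = cm$caveat),
      file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  prof_rows <- list()
  for (p in result$profiles) {
    prof_rows[[length(prof_rows) + 1L]] <- data.frame(
      participant_id = p$participant_id, best_schema = p$best_schema,
      category = names(p$per_category_pct),
      pct = as.numeric(p$per_category_pct))
  }
  if (length(prof_rows)) {
    utils::write.csv(do.call(rbind, prof_rows),
                     file.path(out_dir, "profiles.csv"), row.names = FALSE)
  }
  het_rows <- list()
  for (sg in names(result$heterogeneity)) {
    t <- result$heterogeneity[[sg]]$table
    t$subgroup <- sg
    het_rows[[sg]] <- t
  }
  if (length(het_rows)) {
    utils::write.csv(do.call(rbind, c(het_rows, make.row.names = FALSE)),
                     file.path(out_dir, "heterogeneity.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}
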