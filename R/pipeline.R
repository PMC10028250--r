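# --- end-to-end orchestration with file-based stage contracts -------------
#
# Every stage reads its inputs from and writes its outputs to `out_dir`
# as plain CSV/JSON, so any stage can be rerun or inspected in isolation
# and the subcommands compose to the same result as `run_pipeline()`.

stage_input <- function(stage, out_dir, file) {
  path <- file.path(out_dir, file)
  if (!file.exists(path))
    stop("stage '", stage, "': missing input ", file,
         " (run the preceding stage first)")
  path
}

log_stage <- function(stage, msg, quiet) {
  if (!quiet) message(sprintf("[%s] %s", stage, msg))
}

#' Pipeline stage: simulate a synthetic cohort
#'
#' Writes `subjects.csv`, `strides.csv`, `coordination.csv` and a
#' `config.json` echo of the resolved generator configuration.
#'
#' @param out_dir output directory (created if needed).
#' @param config [generator_config()].
#' @param seed RNG seed.
#' @param quiet suppress progress messages.
#' @return the cohort, invisibly.
#' @export
stage_simulate <- function(out_dir, config = generator_config(),
                           seed = config$seed, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config, seed)
  utils::write.csv(cohort$subjects, file.path(out_dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$strides, file.path(out_dir, "strides.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$coordination),
                   file.path(out_dir, "coordination.csv"),
                   row.names = FALSE)
  jsonlite::write_json(c(unclass(config), list(resolved_seed = seed)),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("simulate", sprintf("%d subjects, %d strides",
                                nrow(cohort$subjects),
                                nrow(cohort$strides)), quiet)
  invisible(cohort)
}

#' Pipeline stage: segment landmark tables into strides
#'
#' Reads every tracker-dialect CSV in `landmark_dir` (file name stem =
#' subject id), segments it, and writes the stride candidate table with
#' gait variables and filter verdicts to `strides_segmented.csv`.
#'
#' @param out_dir output directory.
#' @param landmark_dir directory of landmark CSVs.
#' @param frame_rate,scale passed to [read_landmark_table()].
#' @param quiet suppress progress messages.
#' @param ... thresholds passed to [segment_strides()].
#' @return the stride table, invisibly.
#' @export
stage_segment <- function(out_dir, landmark_dir, frame_rate = 50,
                          scale = 1, quiet = FALSE, ...) {
  files <- list.files(landmark_dir, pattern = "\\.csv$",
                      full.names = TRUE)
  if (!length(files))
    stop("stage 'segment': no landmark CSV files in ", landmark_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- lapply(files, function(f) {
    traj <- read_landmark_table(f, frame_rate = frame_rate, scale = scale)
    segment_strides(traj, sub("\\.csv$", "", basename(f)), ...)
  })
  tab <- do.call(rbind, tabs[!vapply(tabs, is.null, logical(1))])
  utils::write.csv(tab, file.path(out_dir, "strides_segmented.csv"),
                   row.names = FALSE)
  log_stage("segment", sprintf(
    "%d candidates from %d files, %d passed filters",
    nrow(tab), length(files), sum(tab$passed_filters)), quiet)
  invisible(tab)
}

#' Pipeline stage: coordination PCA
#'
#' Reads `strides.csv` and `coordination.csv`, computes the 12
#' coordination components, and writes the model-ready feature table to
#' `features.csv` plus the fitted PCA to `coordination_pca.json`.
#'
#' @param out_dir working directory.
#' @param n_components retained coordination components (default 12).
#' @param quiet suppress progress messages.
#' @return the feature table, invisibly.
#' @export
stage_transform <- function(out_dir, n_components = 12, quiet = FALSE) {
  strides <- utils::read.csv(stage_input("transform", out_dir,
                                         "strides.csv"))
  coords <- as.matrix(utils::read.csv(stage_input("transform", out_dir,
                                                  "coordination.csv")))
  cp <- coordination_pca(coords, n_components)
  features <- cbind(strides, as.data.frame(cp$scores))
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  pca_to_json(cp$model, file.path(out_dir, "coordination_pca.json"))
  log_stage("transform", sprintf(
    "%d strides, %d coordination components (%.1f%% variance)",
    nrow(features), n_components, 100 * cp$explained), quiet)
  invisible(features)
}

#' Pipeline stage: fit one subject-characteristic model
#'
#' Reads `features.csv`, splits it (NBW train / NBW validation / LBW
#' test), fits the model on the training set and writes the posterior
#' draws (`posterior_<outcome>.csv`), diagnostics and split assignment.
#'
#' @param out_dir working directory.
#' @param outcome `"mass"`, `"size"` or `"age"`.
#' @param chains,tune,draws,profile MCMC settings, see
#'   [sample_posterior()].
#' @param seed RNG seed (split and sampler).
#' @param quiet suppress progress messages.
#' @return the posterior bundle, invisibly.
#' @export
stage_fit <- function(out_dir, outcome = "age", chains = 4, tune = 1000,
                      draws = 1000, profile = "desk", seed = 1,
                      quiet = FALSE) {
  features <- utils::read.csv(stage_input("fit", out_dir, "features.csv"))
  sets <- split_dataset(features, seed = seed)
  features$set <- "train"
  features$set[features$stride_id %in% sets$validation$stride_id] <-
    "validation"
  features$set[features$stride_id %in% sets$test$stride_id] <- "test"
  utils::write.csv(features[, c("stride_id", "set")],
                   file.path(out_dir, "split.csv"), row.names = FALSE)
  design <- model_design(outcome)
  model <- build_model(design, sets$train)
  bundle <- sample_posterior(model, chains = chains, tune = tune,
                             draws = draws, seed = seed,
                             profile = profile)
  utils::write.csv(as.data.frame(bundle$draws),
                   file.path(out_dir, paste0("posterior_", outcome,
                                             ".csv")), row.names = FALSE)
  utils::write.csv(bundle$diagnostics,
                   file.path(out_dir, paste0("diagnostics_", outcome,
                                             ".csv")), row.names = FALSE)
  jsonlite::write_json(
    list(outcome = outcome, transform = design$transform,
         predictors = design$predictors, n_train = model$n_train,
         n_parameters = model$n_parameters, chains = bundle$chains,
         tune = bundle$tune, draws = bundle$n_draws, seed = seed,
         failed = bundle$failed,
         x_center = model$x_center, x_scale = model$x_scale,
         y_center = model$y_center, y_scale = model$y_scale),
    file.path(out_dir, paste0("model_", outcome, ".json")),
    auto_unbox = TRUE, digits = NA)
  log_stage("fit", sprintf(
    "%s: %d train / %d validation / %d test strides, max R-hat %.3f",
    outcome, nrow(sets$train), nrow(sets$validation), nrow(sets$test),
    suppressWarnings(max(bundle$diagnostics$rhat, na.rm = TRUE))), quiet)
  invisible(bundle)
}

#' Pipeline stage: posterior-predictive inference for every stride
#'
#' Requires [stage_fit()] to have been run in this session directory;
#' re-uses its in-memory bundle when supplied, otherwise refits from the
#' stored draws is not attempted (draw files are for inspection).
#'
#' @param out_dir working directory.
#' @param bundle [sample_posterior()] output for the outcome.
#' @param seed RNG seed for predictive noise.
#' @param quiet suppress progress messages.
#' @return the per-stride inference table, invisibly.
#' @export
stage_predict <- function(out_dir, bundle, seed = 1, quiet = FALSE) {
  features <- utils::read.csv(stage_input("predict", out_dir,
                                          "features.csv"))
  split <- utils::read.csv(stage_input("predict", out_dir, "split.csv"))
  pred <- predict_strides(bundle, features, seed = seed)
  pred$set <- split$set[match(pred$stride_id, split$stride_id)]
  outcome <- bundle$model$design$outcome
  utils::write.csv(pred, file.path(out_dir, paste0("predictions_",
                                                   outcome, ".csv")),
                   row.names = FALSE)
  log_stage("predict", sprintf("%s: %d strides", outcome, nrow(pred)),
            quiet)
  invisible(pred)
}

#' Pipeline stage: screening report
#'
#' Writes the per-subject verdict table (`verdicts_<outcome>.csv`) and
#' the per-set Delta summary (`delta_summary_<outcome>.csv`).
#'
#' @param out_dir working directory.
#' @param outcome outcome whose predictions to summarize.
#' @param ratio_threshold see [subject_verdict()].
#' @param quiet suppress progress messages.
#' @return list with `verdicts` and `delta` tables, invisibly.
#' @export
stage_report <- function(out_dir, outcome = "age", ratio_threshold = 0.75,
                         quiet = FALSE) {
  pred <- utils::read.csv(stage_input("report", out_dir,
                                      paste0("predictions_", outcome,
                                             ".csv")))
  verdicts <- subject_verdict(pred, ratio_threshold)
  dh <- delta_histograms(pred, pred$set)
  utils::write.csv(verdicts, file.path(out_dir, paste0("verdicts_",
                                                       outcome, ".csv")),
                   row.names = FALSE)
  utils::write.csv(dh$summary,
                   file.path(out_dir, paste0("delta_summary_", outcome,
                                             ".csv")), row.names = FALSE)
  log_stage("report", sprintf(
    "%s: %d subjects, %d flagged as consistently underestimated",
    outcome, nrow(verdicts), sum(verdicts$consistent_underestimation)),
    quiet)
  invisible(list(verdicts = verdicts, delta = dh$summary))
}

#' Run the full screening pipeline on a synthetic cohort
#'
#' simulate -> transform -> fit -> predict -> report, with all
#' intermediate artifacts written to `out_dir`. Stages compose to the
#' same result when run individually.
#'
#' @param out_dir output directory.
#' @param config [generator_config()].
#' @param outcomes subject characteristics to model (default `"age"`).
#' @param chains,tune,draws MCMC settings.
#' @param seed master seed: cohort, split, sampler and predictive draws.
#' @param quiet suppress progress messages.
#' @return list with per-outcome `verdicts` and `predictions`,
#'   invisibly.
#' @export
run_pipeline <- function(out_dir, config = generator_config(),
                         outcomes = "age", chains = 4, tune = 1000,
                         draws = 1000, seed = 1, quiet = FALSE) {
  stage_simulate(out_dir, config, seed = seed, quiet = quiet)
  stage_transform(out_dir, quiet = quiet)
  out <- list()
  for (oc in outcomes) {
    bundle <- stage_fit(out_dir, oc, chains = chains, tune = tune,
                        draws = draws, seed = seed, quiet = quiet)
    pred <- stage_predict(out_dir, bundle, seed = seed, quiet = quiet)
    rep <- stage_report(out_dir, oc, quiet = quiet)
    out[[oc]] <- list(predictions = pred, verdicts = rep$verdicts,
                      delta = rep$delta)
  }
  invisible(out)
}
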