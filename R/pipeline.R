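#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Errors on degenerate
#' settings before any I/O happens.
#'
#' @param input Path to the cohort CSV (may be `NULL` when subjects are
#'   passed to [run_pipeline()] directly).
#' @param output_dir Directory for pipeline outputs (created if missing).
#' @param constants A [model_constants()] object.
#' @param split_ratio Experimental-group fraction, strictly in (0, 1).
#' @param split_seed Integer seed for the random split.
#' @param outlier_field Column screened for outliers (default pulse
#'   pressure).
#' @param outlier_z Z-score exclusion threshold (default 3).
#' @param calibration_source `"fit_from_data"` (fit group models on the
#'   experimental split; requires measured viscosity) or `"reference"`
#'   (use the literature-fixed coefficients).
#' @param alpha Significance level for balance checks.
#' @param balance_parameters Columns checked for between-group balance.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, output_dir = tempfile("microvisc_"),
                            constants = model_constants(),
                            split_ratio = 0.5, split_seed = 1L,
                            outlier_field = "pp_mmHg", outlier_z = 3,
                            calibration_source = c("fit_from_data",
                                                   "reference"),
                            alpha = 0.05,
                            balance_parameters = c("bmi", "pp_mmHg",
                                                   "co_ml_min")) {
  calibration_source <- match.arg(calibration_source)
  if (!is.numeric(split_ratio) || split_ratio <= 0 || split_ratio >= 1) {
    stop("configuration error: split_ratio must lie strictly in (0, 1)")
  }
  if (!is.numeric(outlier_z) || outlier_z <= 0) {
    stop("configuration error: outlier_z must be positive")
  }
  structure(list(input = input, output_dir = output_dir,
                 constants = constants, split_ratio = split_ratio,
                 split_seed = as.integer(split_seed),
                 outlier_field = outlier_field, outlier_z = outlier_z,
                 calibration_source = calibration_source, alpha = alpha,
                 balance_parameters = balance_parameters),
            class = "pipeline_config")
}

.stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full estimation and validation pipeline
#'
#' Executes, in order: cohort loading (unless `subjects` is supplied),
#' hemodynamic derivation, z-score outlier exclusion, removal of
#' thin-class subjects (no calibration model exists for them), the seeded
#' experimental/validation split with balance verification, calibration
#' (fit on the experimental split, or the literature-fixed reference
#' coefficients), personalized viscosity estimation, and -- when measured
#' viscosities are available -- the Pearson-correlation validation.
#' Writes `models.json`, `per_subject.csv` and `summary.json` into the
#' configured output directory; every input subject appears exactly once
#' in the per-subject table with a status
#' (`ok`, `row-error`, `excluded-outlier`, `unsupported-class`,
#' `invalid-r6`). Fully reproducible: identical inputs and config give
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param subjects Optional subject data frame, bypassing the CSV reader.
#' @return The pipeline report (list with `models`, `split`, `balance`,
#'   `per_subject`, `summary`, `paths`), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), subjects = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  constants <- config$constants

  status <- list()  # subject_id -> status, in first-seen order
  note_status <- function(ids, st) {
    for (id in ids) if (is.null(status[[id]])) status[[id]] <<- st
  }

  # -- load ------------------------------------------------------------
  if (is.null(subjects)) {
    if (is.null(config$input)) {
      stop("[load] no input: config$input is NULL and no subjects supplied")
    }
    loaded <- read_cohort(config$input)
    subjects <- loaded$subjects
    if (loaded$partial) {
      .stage_msg("load", "rejected %d row(s); see per-subject output",
                 nrow(loaded$rejected))
      note_status(loaded$rejected$subject_id, "row-error")
    }
    .stage_msg("load", "%d valid subject(s) from %s", nrow(subjects),
               config$input)
  } else {
    issues <- validate_subjects(subjects)
    if (nrow(issues)) {
      note_status(issues$subject_id, "row-error")
      subjects <- subjects[-issues$row, , drop = FALSE]
      .stage_msg("load", "rejected %d invalid in-memory record(s)",
                 nrow(issues))
    }
  }
  if (nrow(subjects) == 0L) stop("[load] no valid subjects")
  input_order <- c(names(status), as.character(subjects$subject_id))

  # -- derive ----------------------------------------------------------
  derived <- derive_hemodynamics(subjects, constants)
  .stage_msg("derive", "derived parameters for %d subject(s)", nrow(derived))

  # -- outliers --------------------------------------------------------
  ex <- exclude_outliers(derived, field = config$outlier_field,
                         z_threshold = config$outlier_z, constants = constants)
  if (nrow(ex$excluded)) {
    for (i in seq_len(nrow(ex$excluded))) {
      .stage_msg("outliers", "excluded %s: %s", ex$excluded$subject_id[i],
                 ex$excluded$reason[i])
    }
  }
  note_status(ex$excluded$subject_id, "excluded-outlier")
  kept <- ex$kept

  # -- thin class ------------------------------------------------------
  thin <- kept$bmi_class == "thin"
  if (any(thin)) {
    .stage_msg("classify", "%d thin-class subject(s) unsupported", sum(thin))
    note_status(kept$subject_id[thin], "unsupported-class")
    kept <- kept[!thin, , drop = FALSE]
  }

  # -- split + balance -------------------------------------------------
  split <- random_split(kept, ratio = config$split_ratio,
                        seed = config$split_seed)
  .stage_msg("split", "%d experimental / %d validation (seed %d)",
             length(split$experimental_ids), length(split$validation_ids),
             split$seed)
  balance <- check_balance(split, kept, config$balance_parameters,
                           alpha = config$alpha, constants = constants)
  for (i in seq_len(nrow(balance))) {
    .stage_msg("balance", "%s: %s (var p = %.3f, mean p = %.3f)",
               balance$parameter[i],
               if (balance$balanced[i]) "balanced" else "IMBALANCED",
               balance$variance_test_p[i], balance$mean_test_p[i])
  }

  # -- calibrate -------------------------------------------------------
  have_mu <- "measured_viscosity_cp" %in% names(kept) &&
    any(!is.na(kept$measured_viscosity_cp))
  if (config$calibration_source == "fit_from_data") {
    if (!have_mu) {
      stop("[calibrate] calibration_source = fit_from_data requires ",
           "measured_viscosity_cp in the input")
    }
    exp_set <- kept[kept$subject_id %in% split$experimental_ids, , drop = FALSE]
    models <- list(overweight = fit_group(build_design(exp_set, 1L, constants)),
                   normal = fit_group(build_design(exp_set, 0L, constants)))
    .stage_msg("calibrate",
               "fitted group models on experimental split (n = %d, %d)",
               models$overweight$fit_n, models$normal$fit_n)
  } else {
    models <- reference_models()
    .stage_msg("calibrate", "using literature-fixed reference coefficients")
  }

  # -- estimate + validate ---------------------------------------------
  if (have_mu) {
    report <- run_validation(kept, models, constants, split = split)
    per <- report$per_subject
    summary_stats <- report$summary
  } else {
    .stage_msg("validate",
               "no measured viscosity: estimation-only mode, validation skipped")
    pv <- personalized_viscosity(kept, models, constants)
    per <- data.frame(subject_id = pv$subject_id,
                      group = kept$bmi_indicator,
                      set = ifelse(pv$subject_id %in% split$experimental_ids,
                                   "experimental", "validation"),
                      predicted_r6 = pv$r6, target_r6 = NA_real_,
                      mu_personalized_cp = pv$mu_cp,
                      mu_measured_cp = NA_real_, valid = pv$valid,
                      stringsAsFactors = FALSE)
    summary_stats <- list(r_r6 = NA_real_, p_r6 = NA_real_, r_mu = NA_real_,
                          p_mu = NA_real_, n_valid = sum(pv$valid),
                          n_excluded = sum(!pv$valid), sets = NULL)
  }
  note_status(per$subject_id[!per$valid], "invalid-r6")
  note_status(per$subject_id[per$valid], "ok")

  # -- assemble per-subject table over every input subject -------------
  per_all <- data.frame(subject_id = input_order, stringsAsFactors = FALSE)
  per_all$status <- vapply(input_order, function(id) {
    s <- status[[id]]; if (is.null(s)) "excluded-outlier" else s
  }, character(1))
  per_all <- merge(per_all, per, by = "subject_id", all.x = TRUE,
                   sort = FALSE)
  per_all <- per_all[match(input_order, per_all$subject_id), , drop = FALSE]
  rownames(per_all) <- NULL

  # -- write outputs ---------------------------------------------------
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(models = file.path(config$output_dir, "models.json"),
                per_subject = file.path(config$output_dir, "per_subject.csv"),
                summary = file.path(config$output_dir, "summary.json"))
  write_models_json(models, paths$models)
  utils::write.csv(per_all, paths$per_subject, row.names = FALSE, quote = FALSE)
  summary_json <- list(
    n_input = length(input_order),
    n_analyzed = nrow(kept),
    n_experimental = length(split$experimental_ids),
    n_validation = length(split$validation_ids),
    calibration_source = config$calibration_source,
    split_seed = config$split_seed, split_ratio = config$split_ratio,
    outlier = list(field = config$outlier_field, z = config$outlier_z,
                   excluded = as.list(ex$excluded$subject_id)),
    balance = balance,
    correlations = summary_stats)
  jsonlite::write_json(summary_json, paths$summary, auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "rows")
  .stage_msg("write", "outputs in %s", config$output_dir)

  invisible(list(models = models, split = split, balance = balance,
                 per_subject = per_all, summary = summary_stats,
                 paths = paths))
}
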