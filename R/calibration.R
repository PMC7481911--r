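#' @title BMI-stratified calibration of the simulated radius
#' @name calibration
#' @description
#' The latent tube radius R of the capillary-network model cannot be
#' measured, so its sixth power is calibrated by ordinary least squares
#' against clinically measured viscosity, separately for the overweight
#' (BMI >= 25) and normal (18.5 <= BMI < 25) strata:
#' \deqn{R^6_{1} = a_1 + b_1\,SV/PP + c_1\,HR \quad (overweight)}
#' \deqn{R^6_{0} = a_0 + b_0\,SV/PP + c_0\,W  \quad (normal)}
#' The reference coefficients are (-0.334, 0.196, 0.004) and
#' (-0.18, 0.151, 0.003). No model exists for the thin class.
NULL

.new_calibration_model <- function(group, intercept, coeff_sv_pp,
                                   coeff_second, fit_n = NA_integer_,
                                   r_squared = NA_real_, coef_se = NULL) {
  stopifnot(group %in% c(0L, 1L))
  structure(list(
    group = as.integer(group),
    intercept = intercept,
    coeff_sv_pp = coeff_sv_pp,
    coeff_second = coeff_second,
    second_predictor = if (group == 1L) "HR" else "W",
    fit_n = fit_n,
    r_squared = r_squared,
    coef_se = coef_se
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "Calibration model (group %d, %s): R6 = %.3f + %.3f * SV/PP + %.3f * %s\n",
    x$group, if (x$group == 1L) "overweight" else "normal",
    x$intercept, x$coeff_sv_pp, x$coeff_second, x$second_predictor))
  if (!is.na(x$fit_n)) {
    cat(sprintf("  fitted on n = %d, R^2 = %.3f\n", x$fit_n, x$r_squared))
  } else {
    cat("  literature-fixed coefficients (not fitted here)\n")
  }
  invisible(x)
}

#' Reference calibration models
#'
#' The published coefficients of the two stratified regression equations,
#' flagged as literature-fixed (`fit_n` absent). Group 1 (overweight)
#' regresses R^6 on SV/PP and heart rate; group 0 (normal) on SV/PP and
#' weight.
#'
#' @return Named list with elements `overweight` and `normal`, each a
#'   `calibration_model`.
#' @examples
#' reference_models()$overweight$intercept  # -0.334
#' @export
reference_models <- function() {
  list(
    overweight = .new_calibration_model(1L, -0.334, 0.196, 0.004),
    normal     = .new_calibration_model(0L, -0.18, 0.151, 0.003)
  )
}

#' Build the regression design for one BMI stratum
#'
#' One row per subject in the requested group: the regressors (SV/PP and
#' heart rate for the overweight group, SV/PP and weight for the normal
#' group) and the target R^6 obtained by inverting the closed form at the
#' subject's measured viscosity. Subjects without a measured viscosity are
#' excluded with a logged reason; thin-class subjects are an error because
#' no model is defined for them.
#'
#' @param subjects Subject data frame; derived columns are computed if
#'   absent. Must contain `measured_viscosity_cp`.
#' @param group_indicator 1 (overweight) or 0 (normal).
#' @param constants A [model_constants()] object.
#' @return Data frame with columns `subject_id`, `sv_over_pp`,
#'   `second_value`, `target_r6`; attribute `excluded` lists subjects
#'   dropped for missing viscosity.
#' @export
build_design <- function(subjects, group_indicator,
                         constants = model_constants()) {
  stopifnot(group_indicator %in% c(0L, 1L))
  if (!"bmi_indicator" %in% names(subjects)) {
    subjects <- derive_hemodynamics(subjects, constants)
  }
  if (!"measured_viscosity_cp" %in% names(subjects)) {
    stop("subjects lack a measured_viscosity_cp column; cannot calibrate")
  }
  if (any(subjects$bmi_class == "thin")) {
    stop("thin-class subject(s) in calibration input: no model is defined ",
         "for BMI < 18.5")
  }
  grp <- subjects[subjects$bmi_indicator == group_indicator, , drop = FALSE]
  has_mu <- !is.na(grp$measured_viscosity_cp)
  excluded <- grp$subject_id[!has_mu]
  if (length(excluded)) {
    message("build_design: excluded ", length(excluded),
            " subject(s) lacking measured viscosity: ",
            paste(excluded, collapse = ", "))
  }
  grp <- grp[has_mu, , drop = FALSE]
  second <- if (group_indicator == 1L) grp$heart_rate_bpm else grp$weight_kg
  design <- data.frame(
    subject_id = as.character(grp$subject_id),
    sv_over_pp = grp$sv_ml / grp$pp_mmHg,
    second_value = second,
    target_r6 = if (nrow(grp)) {
      invert_r6(grp$measured_viscosity_cp, grp$bsa_m2, grp$co_ml_min,
                grp$pp_mmHg, constants)
    } else numeric(0),
    stringsAsFactors = FALSE
  )
  attr(design, "excluded") <- as.character(excluded)
  attr(design, "group") <- as.integer(group_indicator)
  design
}

#' Fit a group's calibration model by ordinary least squares
#'
#' Plain OLS of the target R^6 on the two group regressors, matching the
#' original multiple-regression calibration. No regularization, no robust
#' errors, no standardization: coefficients are on raw scales.
#'
#' @param design A design data frame from [build_design()].
#' @return A `calibration_model` with fit diagnostics (`fit_n`,
#'   `r_squared`, `coef_se`).
#' @export
fit_group <- function(design) {
  group <- attr(design, "group")
  if (is.null(group)) stop("design lacks a group attribute; use build_design()")
  if (nrow(design) < 3L) {
    stop("insufficient data: need at least 3 rows to fit 3 coefficients, got ",
         nrow(design))
  }
  X <- cbind(1, design$sv_over_pp, design$second_value)
  qr_x <- qr(X)
  if (qr_x$rank < 3L) {
    cols <- c("intercept", "sv_over_pp", "second_value")
    stop("rank-deficient design: collinear column(s) among ",
         paste(cols, collapse = ", "))
  }
  fit <- stats::lm(target_r6 ~ sv_over_pp + second_value, data = design)
  cf <- stats::coef(fit)
  sm <- summary(fit)
  .new_calibration_model(
    group = group,
    intercept = unname(cf[1]),
    coeff_sv_pp = unname(cf[2]),
    coeff_second = unname(cf[3]),
    fit_n = nrow(design),
    r_squared = sm$r.squared,
    coef_se = unname(sm$coefficients[, "Std. Error"])
  )
}

#' Predict R^6 for subjects from a calibration model
#'
#' Affine prediction `intercept + b * SV/PP + c * (HR or W)`. Every subject
#' must belong to the model's BMI group; predictions can be nonpositive
#' when extrapolating, and callers must treat those as invalid (see
#' [closed_form_viscosity()]). The subject's own measured viscosity, if
#' any, never enters the prediction.
#'
#' @param model A `calibration_model`.
#' @param subjects Subject data frame; derived columns computed if absent.
#' @param constants A [model_constants()] object.
#' @return Numeric vector of predicted R^6, one per subject row.
#' @export
predict_r6 <- function(model, subjects, constants = model_constants()) {
  stopifnot(inherits(model, "calibration_model"))
  if (!"bmi_indicator" %in% names(subjects)) {
    subjects <- derive_hemodynamics(subjects, constants)
  }
  if (any(subjects$bmi_class == "thin")) {
    stop("thin-class subject(s): no calibration model for BMI < 18.5")
  }
  if (any(subjects$bmi_indicator != model$group)) {
    stop("BMI class mismatch: model is for group ", model$group,
         " but some subjects belong to the other group")
  }
  second <- if (model$group == 1L) subjects$heart_rate_bpm else subjects$weight_kg
  model$intercept + model$coeff_sv_pp * (subjects$sv_ml / subjects$pp_mmHg) +
    model$coeff_second * second
}

#' Personalized viscosity estimate
#'
#' The full personalized prediction: pick the subject's group model, predict
#' R^6 from the group regressors, and evaluate the closed form
#' `mu' = k * R^6 * PP / (BSA * CO)`. Thin-class subjects are unsupported;
#' a nonpositive predicted R^6 yields an invalid-flagged result.
#'
#' @param subjects Subject data frame; derived columns computed if absent.
#' @param models Named list with `overweight` and `normal`
#'   `calibration_model`s (default [reference_models()]).
#' @param constants A [model_constants()] object.
#' @return A `viscosity_result` data frame (provenance `"personalized"`)
#'   with an additional `subject_id` column, row order matching the input.
#' @examples
#' s <- data.frame(subject_id = "s1", height_cm = 168.8, weight_kg = 74.11,
#'                 heart_rate_bpm = 72.1, sbp_mmHg = 128.59, dbp_mmHg = 74.16,
#'                 lv_edd_mm = 50.27, lv_esd_mm = 34.12)
#' personalized_viscosity(s)
#' @export
personalized_viscosity <- function(subjects, models = reference_models(),
                                   constants = model_constants()) {
  stopifnot(is.list(models), all(c("overweight", "normal") %in% names(models)))
  if (!"bmi_indicator" %in% names(subjects)) {
    subjects <- derive_hemodynamics(subjects, constants)
  }
  if (any(subjects$bmi_class == "thin")) {
    stop("thin-class subject(s): personalized viscosity is undefined for ",
         "BMI < 18.5")
  }
  r6 <- rep(NA_real_, nrow(subjects))
  for (g in c(1L, 0L)) {
    idx <- subjects$bmi_indicator == g
    if (any(idx)) {
      m <- if (g == 1L) models$overweight else models$normal
      r6[idx] <- predict_r6(m, subjects[idx, , drop = FALSE], constants)
    }
  }
  res <- closed_form_viscosity(r6, subjects$pp_mmHg, subjects$bsa_m2,
                               subjects$co_ml_min, constants,
                               provenance = "personalized")
  res$subject_id <- as.character(subjects$subject_id)
  res[, c("subject_id", "mu_cp", "r6", "valid", "provenance")]
}

#' Serialize calibration models to JSON
#'
#' @param models Named list of `calibration_model`s (as from
#'   [reference_models()] or fitting).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_models_json <- function(models, path) {
  payload <- lapply(models, function(m) {
    list(group = m$group, intercept = m$intercept,
         coeff_sv_pp = m$coeff_sv_pp, coeff_second = m$coeff_second,
         second_predictor = m$second_predictor,
         fit_n = if (is.na(m$fit_n)) NULL else m$fit_n,
         r_squared = if (is.na(m$r_squared)) NULL else m$r_squared)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read calibration models from JSON
#'
#' @param path JSON file written by [write_models_json()].
#' @return Named list of `calibration_model`s.
#' @export
read_models_json <- function(path) {
  stopifnot(file.exists(path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw, function(m) {
    .new_calibration_model(
      group = m$group, intercept = m$intercept,
      coeff_sv_pp = m$coeff_sv_pp, coeff_second = m$coeff_second,
      fit_n = if (is.null(m$fit_n)) NA_integer_ else as.integer(m$fit_n),
      r_squared = if (is.null(m$r_squared)) NA_real_ else m$r_squared)
  })
  stopifnot(all(c("overweight", "normal") %in% names(out)))
  out
}
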