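#' @title Seeded synthetic-cohort generator with planted ground truth
#' @name synthetic_cohort
#' @description
#' Generates cohorts of subject records whose marginal moments match the
#' published cohort summary (79 male cardiovascular patients), with
#' physiologically plausible cross-correlations, and plants a known
#' R^6 / viscosity ground truth through the group calibration models so the
#' whole calibration and validation pipeline can be exercised end to end
#' without any clinical data.
NULL

#' Default cohort specification
#'
#' Target marginal moments (mean, SD) per clinical variable, taken from the
#' published cohort summary: height 168.80 +- 5.87 cm, weight
#' 74.11 +- 10.84 kg, heart rate 72.10 +- 7.50 beat/min, SBP
#' 128.59 +- 15.04 mmHg, DBP 74.16 +- 10.15 mmHg, LV end-diastolic
#' diameter 50.27 +- 5.73 mm, LV end-systolic diameter 34.12 +- 6.36 mm;
#' n = 79. Pairwise correlations (height, weight) 0.5, (SBP, DBP) 0.6,
#' (EDD, ESD) 0.7 are plausible physiological defaults -- the source gives
#' none -- and all other pairs are uncorrelated. `overweight_fraction` is
#' the reported target share with BMI >= 25 (0.55); the realized share is
#' induced by the height/weight joint, not forced per row.
#'
#' @param n Cohort size (default 79).
#' @param overweight_fraction Target overweight share (reporting only).
#' @return Object of class `cohort_spec`.
#' @export
default_cohort_spec <- function(n = 79L, overweight_fraction = 0.55) {
  stopifnot(n >= 1L, overweight_fraction > 0, overweight_fraction < 1)
  moments <- data.frame(
    variable = c("height_cm", "weight_kg", "heart_rate_bpm",
                 "sbp_mmHg", "dbp_mmHg", "lv_edd_mm", "lv_esd_mm"),
    mean = c(168.80, 74.11, 72.10, 128.59, 74.16, 50.27, 34.12),
    sd   = c(5.87, 10.84, 7.50, 15.04, 10.15, 5.73, 6.36),
    stringsAsFactors = FALSE)
  structure(list(
    n = as.integer(n),
    moments = moments,
    correlations = list(
      c("height_cm", "weight_kg", 0.5),
      c("sbp_mmHg", "dbp_mmHg", 0.6),
      c("lv_edd_mm", "lv_esd_mm", 0.7)),
    overweight_fraction = overweight_fraction
  ), class = "cohort_spec")
}

#' Generator configuration
#'
#' @param seed Integer seed; identical (spec, config) pairs generate
#'   byte-identical cohorts.
#' @param r6_noise_sd SD of the additive Gaussian noise on the planted R^6.
#'   The default 0.045 was fixed once by calibrating, with
#'   [calibrate_noise_for_target_r()], the mean validation-set correlation
#'   r(mu', mu) of the default pipeline to the published headline value
#'   0.443 (+- 0.05); two independent 150-replicate sets achieve ~0.44.
#' @param viscosity_noise_sd SD of additive measurement noise on the
#'   measured viscosity, cp (default 0: measurement error is folded into
#'   the R^6 noise, which is the quantity the calibration sees).
#' @param planted_models Calibration models used as planted truth (default
#'   [reference_models()]).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, r6_noise_sd = 0.045,
                             viscosity_noise_sd = 0,
                             planted_models = reference_models()) {
  stopifnot(r6_noise_sd >= 0, viscosity_noise_sd >= 0,
            all(c("overweight", "normal") %in% names(planted_models)))
  structure(list(seed = as.integer(seed), r6_noise_sd = r6_noise_sd,
                 viscosity_noise_sd = viscosity_noise_sd,
                 planted_models = planted_models),
            class = "generator_config")
}

.spec_sigma <- function(spec) {
  vars <- spec$moments$variable
  k <- length(vars)
  corr <- diag(k)
  dimnames(corr) <- list(vars, vars)
  for (p in spec$correlations) {
    i <- match(p[[1]], vars); j <- match(p[[2]], vars)
    rho <- as.numeric(p[[3]])
    stopifnot(!is.na(i), !is.na(j), abs(rho) < 1)
    corr[i, j] <- corr[j, i] <- rho
  }
  d <- diag(spec$moments$sd)
  d %*% corr %*% d
}

# One batch of multivariate-normal candidate rows (chol factor precomputed).
.draw_batch <- function(m, mu, chol_u, vars) {
  z <- matrix(stats::rnorm(m * length(mu)), nrow = m)
  x <- z %*% chol_u
  x <- sweep(x, 2, mu, "+")
  colnames(x) <- vars
  as.data.frame(x)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws correlated Gaussian clinical variables with the spec's moments and
#' rejects (never clamps) candidate rows violating any record invariant:
#' positivity, SBP > DBP, EDD > ESD, and BMI >= 18.5 (the calibration
#' defines no model for the thin class, and the emulated cohort contained
#' none). For each accepted row the planted truth is
#' `true_r6 = group model prediction + N(0, r6_noise_sd)` (rows with
#' nonpositive `true_r6` are also rejected) and
#' `true_mu = k * true_r6 * PP / (BSA * CO)`; the recorded
#' `measured_viscosity_cp` adds `N(0, viscosity_noise_sd)` and must stay
#' positive. Fully deterministic under the config seed; the caller's RNG
#' state is untouched.
#'
#' @param spec A [default_cohort_spec()] object.
#' @param config A [generator_config()] object.
#' @param constants A [model_constants()] object.
#' @return List with `subjects` (subject data frame incl.
#'   `measured_viscosity_cp`) and `truth` (data frame `subject_id`,
#'   `true_r6`, `true_mu_cp`, `group`).
#' @examples
#' gc <- generate_cohort(default_cohort_spec(n = 20), generator_config(7))
#' head(gc$subjects)
#' @export
generate_cohort <- function(spec = default_cohort_spec(),
                            config = generator_config(),
                            constants = model_constants()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(config, "generator_config"))
  vars <- spec$moments$variable
  mu <- spec$moments$mean
  chol_u <- chol(.spec_sigma(spec))
  pm <- config$planted_models
  withr::with_seed(config$seed, {
    acc <- list()
    n_acc <- 0L
    n_tried <- 0L
    while (n_acc < spec$n) {
      m <- max(2L * (spec$n - n_acc), 100L)
      df <- .draw_batch(m, mu, chol_u, vars)
      eps_r6 <- stats::rnorm(m, 0, config$r6_noise_sd)
      eps_mu <- stats::rnorm(m, 0, config$viscosity_noise_sd)
      n_tried <- n_tried + m
      ok <- rowSums(as.matrix(df) <= 0) == 0 &
        df$sbp_mmHg > df$dbp_mmHg & df$lv_edd_mm > df$lv_esd_mm
      if (any(ok)) {
        d <- df[ok, , drop = FALSE]
        bmi <- d$weight_kg / (d$height_cm / 100)^2
        keep <- bmi >= 18.5
        d <- d[keep, , drop = FALSE]
        e_r6 <- eps_r6[ok][keep]
        e_mu <- eps_mu[ok][keep]
        if (nrow(d)) {
          grp <- as.integer(bmi[keep] >= 25)
          sv <- compute_sv(d$lv_edd_mm, d$lv_esd_mm, constants)
          pp <- d$sbp_mmHg - d$dbp_mmHg
          co <- sv * d$heart_rate_bpm
          bsa <- compute_bsa(d$height_cm, d$weight_kg, constants)
          sv_pp <- sv / pp
          r6_mean <- ifelse(
            grp == 1L,
            pm$overweight$intercept + pm$overweight$coeff_sv_pp * sv_pp +
              pm$overweight$coeff_second * d$heart_rate_bpm,
            pm$normal$intercept + pm$normal$coeff_sv_pp * sv_pp +
              pm$normal$coeff_second * d$weight_kg)
          true_r6 <- r6_mean + e_r6
          true_mu <- constants$k_consolidated * true_r6 * pp / (bsa * co)
          measured <- true_mu + e_mu
          keep2 <- true_r6 > 0 & measured > 0
          if (any(keep2)) {
            acc[[length(acc) + 1L]] <- cbind(
              d[keep2, , drop = FALSE],
              data.frame(true_r6 = true_r6[keep2], true_mu = true_mu[keep2],
                         measured = measured[keep2], group = grp[keep2]))
            n_acc <- n_acc + sum(keep2)
          }
        }
      }
      if (n_tried > max(50L * spec$n, 5000L) && n_acc / n_tried < 0.01) {
        stop("infeasible cohort spec: rejection rate above 99%")
      }
    }
    all_rows <- do.call(rbind, acc)[seq_len(spec$n), , drop = FALSE]
    ids <- sprintf("S%04d", seq_len(spec$n))
    subjects <- data.frame(
      subject_id = ids,
      height_cm = all_rows$height_cm, weight_kg = all_rows$weight_kg,
      heart_rate_bpm = all_rows$heart_rate_bpm,
      sbp_mmHg = all_rows$sbp_mmHg, dbp_mmHg = all_rows$dbp_mmHg,
      lv_edd_mm = all_rows$lv_edd_mm, lv_esd_mm = all_rows$lv_esd_mm,
      measured_viscosity_cp = all_rows$measured,
      stringsAsFactors = FALSE)
    truth <- data.frame(subject_id = ids, true_r6 = all_rows$true_r6,
                        true_mu_cp = all_rows$true_mu,
                        group = all_rows$group, stringsAsFactors = FALSE)
    list(subjects = subjects, truth = truth)
  })
}

#' Mean validation-set correlation at a given R^6 noise level
#'
#' Runs the full pipeline (generate, 1:1 split, fit both group models on
#' the experimental set, validate on the validation set) over seeded
#' replicates and returns the mean Pearson r between the personalized and
#' the measured viscosity. The mapping from `r6_noise_sd` to this
#' correlation is monotone decreasing; [calibrate_noise_for_target_r()]
#' inverts it.
#'
#' @param r6_noise_sd Noise SD to evaluate.
#' @param spec A [default_cohort_spec()].
#' @param config A [generator_config()]; its seed anchors the replicate
#'   seeds, its other noise settings are kept.
#' @param replicates Number of seeded replicates (default 50).
#' @return Mean r(mu', mu) across replicates.
#' @export
noise_to_correlation <- function(r6_noise_sd, spec = default_cohort_spec(),
                                 config = generator_config(),
                                 replicates = 50L) {
  stopifnot(r6_noise_sd >= 0, replicates >= 1L)
  rs <- vapply(seq_len(replicates), function(i) {
    seed_i <- (abs(config$seed) * 1009L + i * 7919L) %% 2147483587L
    cfg <- generator_config(seed = seed_i, r6_noise_sd = r6_noise_sd,
                            viscosity_noise_sd = config$viscosity_noise_sd,
                            planted_models = config$planted_models)
    gc <- generate_cohort(spec, cfg)
    subj <- derive_hemodynamics(gc$subjects)
    split <- random_split(subj, ratio = 0.5, seed = seed_i)
    exp_set <- subj[subj$subject_id %in% split$experimental_ids, , drop = FALSE]
    models <- tryCatch(list(
      overweight = fit_group(build_design(exp_set, 1L)),
      normal = fit_group(build_design(exp_set, 0L))), error = function(e) NULL)
    if (is.null(models)) return(NA_real_)
    rep <- run_validation(subj, models, split = split)
    rep$summary$r_mu
  }, numeric(1))
  mean(rs, na.rm = TRUE)
}

#' Calibrate the R^6 noise SD to a target pipeline correlation
#'
#' Bisection over the monotone decreasing mapping from `r6_noise_sd` to the
#' mean validation correlation r(mu', mu) (see [noise_to_correlation()]),
#' under fixed replicate seeds. Used once to fix the generator's default
#' noise at the published headline correlation 0.443; kept as a public
#' operation so the calibration is reproducible.
#'
#' @param target_r Target mean correlation, in (0, 1).
#' @param tol Acceptable absolute deviation of the achieved mean r
#'   (default 0.05).
#' @param spec,config,replicates Passed to [noise_to_correlation()].
#' @param sd_range Search bracket for the noise SD (default c(0, 1)).
#' @param max_iter Bisection iteration cap.
#' @return List with `r6_noise_sd`, `achieved_r`, `iterations`.
#' @export
calibrate_noise_for_target_r <- function(target_r, tol = 0.05,
                                         spec = default_cohort_spec(),
                                         config = generator_config(),
                                         replicates = 50L,
                                         sd_range = c(0, 1),
                                         max_iter = 30L) {
  stopifnot(target_r > 0, target_r < 1, tol > 0, sd_range[1] >= 0,
            sd_range[2] > sd_range[1])
  f <- function(sd) noise_to_correlation(sd, spec, config, replicates)
  r_lo <- f(sd_range[1])   # highest achievable r (least noise)
  if (r_lo <= target_r - tol) {
    stop(sprintf("target_r = %.3f unreachable: r at minimum noise is %.3f",
                 target_r, r_lo))
  }
  if (abs(r_lo - target_r) <= tol && sd_range[1] == 0) {
    return(list(r6_noise_sd = sd_range[1], achieved_r = r_lo, iterations = 0L))
  }
  r_hi <- f(sd_range[2])
  if (r_hi >= target_r + tol) {
    stop(sprintf(
      "target_r = %.3f unreachable: r at maximum noise %.3g is still %.3f",
      target_r, sd_range[2], r_hi))
  }
  lo <- sd_range[1]; hi <- sd_range[2]
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r_mid <- f(mid)
    if (abs(r_mid - target_r) <= tol) {
      return(list(r6_noise_sd = mid, achieved_r = r_mid, iterations = it))
    }
    if (r_mid > target_r) lo <- mid else hi <- mid
  }
  stop(sprintf(
    "bisection did not reach |r - %.3f| <= %.3f in %d iterations; bracket [%.4g, %.4g]",
    target_r, tol, max_iter, lo, hi))
}
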