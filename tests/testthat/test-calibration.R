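test_that("reference models carry the published coefficients, immutably", {
  m <- reference_models()
  expect_equal(m$overweight$intercept, -0.334)
  expect_equal(m$overweight$coeff_sv_pp, 0.196)
  expect_equal(m$overweight$coeff_second, 0.004)
  expect_identical(m$overweight$second_predictor, "HR")
  expect_equal(m$normal$intercept, -0.18)
  expect_equal(m$normal$coeff_sv_pp, 0.151)
  expect_equal(m$normal$coeff_second, 0.003)
  expect_identical(m$normal$second_predictor, "W")
  expect_true(is.na(m$overweight$fit_n))  # literature-fixed, not fitted
  expect_identical(reference_models(), reference_models())
})

test_that("build_design assembles the right regressors and target", {
  gc <- generate_cohort(default_cohort_spec(n = 30), generator_config(11))
  subj <- derive_hemodynamics(gc$subjects)
  for (g in c(1L, 0L)) {
    des <- build_design(subj, g)
    grp <- subj[subj$bmi_indicator == g, ]
    expect_equal(des$sv_over_pp, grp$sv_ml / grp$pp_mmHg)
    expected_second <- if (g == 1L) grp$heart_rate_bpm else grp$weight_kg
    expect_equal(des$second_value, expected_second)
    expect_equal(des$target_r6,
                 invert_r6(grp$measured_viscosity_cp, grp$bsa_m2,
                           grp$co_ml_min, grp$pp_mmHg))
  }
  # subjects lacking measured viscosity are excluded with a message
  subj2 <- subj
  subj2$measured_viscosity_cp[1:3] <- NA
  expect_message(des2 <- build_design(subj2, subj2$bmi_indicator[1]),
                 "lacking measured viscosity")
  expect_setequal(attr(des2, "excluded"), subj2$subject_id[1:3][
    subj2$bmi_indicator[1:3] == subj2$bmi_indicator[1]])
  # no viscosity column at all is an error
  expect_error(build_design(subj[, setdiff(names(subj),
                                           "measured_viscosity_cp")], 1L),
               "measured_viscosity_cp")
  # thin subjects are an error
  thin <- derive_hemodynamics(mean_subject(weight_kg = 45))
  thin$measured_viscosity_cp <- 18
  expect_error(build_design(thin, 0L), "thin")
})

test_that("fit_group recovers zero-noise planted coefficients exactly", {
  set.seed(5)
  n <- 50
  des <- data.frame(subject_id = as.character(seq_len(n)),
                    sv_over_pp = runif(n, 1, 2.5),
                    second_value = runif(n, 55, 95),
                    stringsAsFactors = FALSE)
  des$target_r6 <- -0.334 + 0.196 * des$sv_over_pp + 0.004 * des$second_value
  attr(des, "group") <- 1L
  suppressWarnings(m <- fit_group(des))  # lm warns on a perfect fit
  expect_equal(m$intercept, -0.334, tolerance = 1e-12)
  expect_equal(m$coeff_sv_pp, 0.196, tolerance = 1e-12)
  expect_equal(m$coeff_second, 0.004, tolerance = 1e-12)
  expect_equal(m$fit_n, n)
  expect_identical(m$second_predictor, "HR")
})

test_that("fit_group recovers noisy coefficients within 2 SE at n = 1000", {
  set.seed(6)
  n <- 1000
  des <- data.frame(subject_id = as.character(seq_len(n)),
                    sv_over_pp = runif(n, 1, 2.5),
                    second_value = runif(n, 55, 95),
                    stringsAsFactors = FALSE)
  truth <- c(-0.18, 0.151, 0.003)
  des$target_r6 <- truth[1] + truth[2] * des$sv_over_pp +
    truth[3] * des$second_value + rnorm(n, 0, 0.02)
  attr(des, "group") <- 0L
  m <- fit_group(des)
  est <- c(m$intercept, m$coeff_sv_pp, m$coeff_second)
  expect_true(all(abs(est - truth) <= 2 * m$coef_se))
  expect_identical(m$second_predictor, "W")
})

test_that("fit_group rejects degenerate designs", {
  des <- data.frame(subject_id = c("a", "b", "c", "d"),
                    sv_over_pp = rep(1.7, 4),
                    second_value = c(60, 70, 80, 90),
                    target_r6 = c(0.2, 0.25, 0.3, 0.35))
  attr(des, "group") <- 1L
  expect_error(fit_group(des), "rank-deficient")
  expect_error(fit_group(des[1:2, ]), "insufficient data")
  expect_error(fit_group(data.frame(sv_over_pp = 1)), "group attribute")
})

test_that("predict_r6 matches hand arithmetic including the negative path", {
  m <- reference_models()
  expect_equal(predict_r6(m$overweight, mean_derived(1L)), 0.2864441,
               tolerance = 1e-6)
  expect_equal(predict_r6(m$normal, mean_derived(0L)), 0.2981395,
               tolerance = 1e-6)
  low <- mean_derived(1L)
  low$sv_ml <- 40; low$pp_mmHg <- 80; low$heart_rate_bpm <- 50
  expect_equal(predict_r6(m$overweight, low), -0.036, tolerance = 1e-10)
  # affine in each regressor
  d1 <- mean_derived(1L); d2 <- d1; d3 <- d1
  d2$sv_ml <- d1$sv_ml + d1$pp_mmHg        # sv/pp + 1
  d3$heart_rate_bpm <- d1$heart_rate_bpm + 10
  expect_equal(predict_r6(m$overweight, d2) - predict_r6(m$overweight, d1),
               0.196)
  expect_equal(predict_r6(m$overweight, d3) - predict_r6(m$overweight, d1),
               0.04)
  # class mismatch and thin class are errors
  expect_error(predict_r6(m$overweight, mean_derived(0L)), "mismatch")
  thin <- derive_hemodynamics(mean_subject(weight_kg = 45))
  expect_error(predict_r6(m$normal, thin), "thin")
})

test_that("personalized_viscosity reproduces the worked values per group", {
  pv1 <- personalized_viscosity(mean_derived(1L))
  expect_equal(round(pv1$mu_cp, 2), 19.24)
  expect_identical(pv1$provenance, "personalized")
  pv0 <- personalized_viscosity(mean_derived(0L))
  expect_equal(round(pv0$mu_cp, 2), 20.02)
  # thin subjects unsupported
  expect_error(personalized_viscosity(
    derive_hemodynamics(mean_subject(weight_kg = 45))), "thin")
  # negative predicted r6 flagged invalid, not an error
  low <- mean_derived(1L)
  low$sv_ml <- 40; low$pp_mmHg <- 80; low$heart_rate_bpm <- 50
  pv_low <- personalized_viscosity(low)
  expect_false(pv_low$valid)
})

test_that("measured viscosity never leaks into the prediction", {
  d <- mean_derived(1L)
  d$measured_viscosity_cp <- 18
  d2 <- d
  d2$measured_viscosity_cp <- 35
  expect_identical(personalized_viscosity(d)$mu_cp,
                   personalized_viscosity(d2)$mu_cp)
})

test_that("model JSON serialization round-trips", {
  gc <- generate_cohort(default_cohort_spec(n = 40), generator_config(21))
  subj <- derive_hemodynamics(gc$subjects)
  models <- list(overweight = fit_group(build_design(subj, 1L)),
                 normal = fit_group(build_design(subj, 0L)))
  p <- tempfile(fileext = ".json")
  write_models_json(models, p)
  back <- read_models_json(p)
  for (g in c("overweight", "normal")) {
    expect_equal(back[[g]]$intercept, models[[g]]$intercept)
    expect_equal(back[[g]]$coeff_sv_pp, models[[g]]$coeff_sv_pp)
    expect_equal(back[[g]]$coeff_second, models[[g]]$coeff_second)
    expect_equal(back[[g]]$fit_n, models[[g]]$fit_n)
    expect_identical(back[[g]]$second_predictor, models[[g]]$second_predictor)
  }
})
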