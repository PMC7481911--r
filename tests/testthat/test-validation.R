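test_that("pearson_cor matches hand values and the definitional formula", {
  r <- pearson_cor(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r$r, 0.981981, tolerance = 1e-6)
  expect_equal(r$n, 3L)
  x <- seq(-3, 5, length.out = 20)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  # brute-force definitional oracle on random vectors
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(sample(5:60, 1)); y <- rnorm(length(x))
    brute <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearson_cor(x, y)$r, brute, tolerance = 1e-12)
  }
})

test_that("pearson_cor affine invariance, sign flip and error paths", {
  set.seed(10)
  x <- rnorm(30); y <- rnorm(30)
  r0 <- pearson_cor(x, y)$r
  expect_equal(pearson_cor(3 * x + 2, y)$r, r0)
  expect_equal(pearson_cor(x, 0.5 * y - 7)$r, r0)
  expect_equal(pearson_cor(-2 * x, y)$r, -r0)
  expect_error(pearson_cor(x, rep(1, 30)), "constant")
  expect_error(pearson_cor(x, y[1:10]), "equal length")
  expect_error(pearson_cor(1:2, 2:3), "at least 3")
})

test_that("random_split reproduces the 40/38 sizes and partitions", {
  subj <- data.frame(subject_id = sprintf("p%02d", 1:78))
  sp <- random_split(subj, ratio = 40 / 78, seed = 12)
  expect_length(sp$experimental_ids, 40)
  expect_length(sp$validation_ids, 38)
  expect_length(intersect(sp$experimental_ids, sp$validation_ids), 0)
  expect_setequal(c(sp$experimental_ids, sp$validation_ids),
                  subj$subject_id)
  # determinism and seed sensitivity
  sp2 <- random_split(subj, ratio = 40 / 78, seed = 12)
  expect_identical(sp, sp2)
  sp3 <- random_split(subj, ratio = 40 / 78, seed = 13)
  expect_false(identical(sort(sp$experimental_ids),
                         sort(sp3$experimental_ids)))
  # partition property across seeds and ratios
  for (seed in 1:5) {
    s <- random_split(subj, ratio = 0.5, seed = seed)
    expect_setequal(c(s$experimental_ids, s$validation_ids), subj$subject_id)
    expect_length(s$experimental_ids, 39)
  }
  expect_error(random_split(subj, ratio = 1), "between 0 and 1")
  expect_error(random_split(subj[1:4, , drop = FALSE], 0.5), "at least 6")
})

test_that("exclude_outliers drops a planted extreme pulse pressure", {
  gc <- generate_cohort(default_cohort_spec(n = 79), generator_config(31))
  subj <- derive_hemodynamics(gc$subjects)
  # plant one PP value 6 cohort SDs high (mirrors the 79 -> 78 exclusion)
  i <- 5
  subj$sbp_mmHg[i] <- subj$dbp_mmHg[i] + mean(subj$pp_mmHg) +
    6 * sd(subj$pp_mmHg)
  subj <- derive_hemodynamics(subj[, names(gc$subjects)])
  res <- exclude_outliers(subj, "pp_mmHg", 3)
  expect_equal(nrow(res$kept), 78)
  expect_equal(res$excluded$subject_id, subj$subject_id[i])
  expect_match(res$excluded$reason, "pp_mmHg")
  # homogeneous cohort: nothing excluded
  res2 <- exclude_outliers(derive_hemodynamics(gc$subjects), "pp_mmHg", 3)
  expect_equal(nrow(res2$excluded), 0)
  expect_error(exclude_outliers(subj, "pp_mmHg", 0), "positive")
  # zero-SD field warns and keeps everything
  subj$flat <- 1
  expect_warning(res3 <- exclude_outliers(subj, "flat", 3), "zero")
  expect_equal(nrow(res3$kept), nrow(subj))
})

test_that("check_balance flags planted shifts and passes identical groups", {
  subj <- small_cohort(40)
  sp <- random_split(subj, 0.5, seed = 2)
  # identical distributions by construction of the copied halves:
  dup <- subj
  dup$subject_id <- sprintf("d%02d", 1:40)
  both <- rbind(subj, dup)
  sp_ident <- structure(list(experimental_ids = subj$subject_id,
                             validation_ids = dup$subject_id,
                             seed = 1L, ratio = 0.5), class = "split_result")
  rep_ident <- check_balance(sp_ident, both, c("bmi", "pp_mmHg"))
  expect_true(all(rep_ident$balanced))
  expect_equal(rep_ident$var_experimental, rep_ident$var_validation)
  # planted 3-SD mean shift is flagged
  shifted <- both
  sel <- shifted$subject_id %in% dup$subject_id
  shifted$weight_kg[sel] <- shifted$weight_kg[sel] + 3 * sd(subj$weight_kg)
  rep_shift <- check_balance(sp_ident, shifted, "weight_kg")
  expect_false(rep_shift$balanced)
  expect_lt(rep_shift$mean_test_p, 0.05)
  expect_error(check_balance(sp, subj, "no_such_column"), "unknown parameter")
})

test_that("under the null, each balance test rejects at about alpha", {
  # one population, two groups of 60; 2000 seeded replicates on one variable
  reps <- 2000
  n <- 60
  rej <- withr::with_seed(77, {
    out <- matrix(NA_real_, reps, 2)
    for (i in seq_len(reps)) {
      x <- rnorm(2 * n, 100, 10)
      g <- rep(c("a", "b"), each = n)
      lev <- microvisc:::levene_test(x, g)
      wel <- t.test(x[g == "a"], x[g == "b"])
      out[i, ] <- c(lev$p_value < 0.05, wel$p.value < 0.05)
    }
    colMeans(out)
  })
  expect_lt(abs(rej[1] - 0.05), 0.02)  # Levene
  expect_lt(abs(rej[2] - 0.05), 0.02)  # Welch
})

test_that("run_validation is exact on a noiseless cohort and labels sets", {
  gc <- generate_cohort(default_cohort_spec(n = 60),
                        generator_config(41, r6_noise_sd = 0))
  subj <- derive_hemodynamics(gc$subjects)
  sp <- random_split(subj, 0.5, seed = 3)
  rep <- run_validation(subj, reference_models(), split = sp)
  expect_equal(rep$summary$r_r6, 1, tolerance = 1e-9)
  expect_equal(rep$summary$r_mu, 1, tolerance = 1e-9)
  expect_lt(rep$summary$p_r6, 1e-6)
  expect_setequal(names(rep$summary$sets),
                  c("validation", "experimental", "all"))
  expect_equal(rep$summary$sets$all$r_mu, 1, tolerance = 1e-9)
  expect_setequal(unique(rep$per_subject$set),
                  c("validation", "experimental"))
  # every analyzed subject appears once
  expect_setequal(rep$per_subject$subject_id, subj$subject_id)
  # invalid predictions are excluded and counted
  lowmod <- reference_models()
  lowmod$overweight$intercept <- -10  # force negative predictions in group 1
  rep2 <- run_validation(subj, lowmod, split = sp)
  expect_gt(rep2$summary$n_excluded, 0)
  expect_equal(rep2$summary$n_valid + rep2$summary$n_excluded,
               sum(rep$per_subject$set == "validation"))
  # cohort without measured viscosity errors
  bare <- subj[, setdiff(names(subj), "measured_viscosity_cp")]
  expect_error(run_validation(bare, reference_models()),
               "measured_viscosity_cp")
})
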