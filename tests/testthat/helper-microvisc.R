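# Builders for in-code fixtures; no stored data files.

# One subject at the published cohort means (raw measurements).
mean_subject <- function(subject_id = "s1", ...) {
  base <- data.frame(
    subject_id = subject_id,
    height_cm = 168.80, weight_kg = 74.11, heart_rate_bpm = 72.10,
    sbp_mmHg = 128.59, dbp_mmHg = 74.16,
    lv_edd_mm = 50.27, lv_esd_mm = 34.12,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# A derived-parameter frame built directly from model-parameter values,
# bypassing the raw record (for testing calibration arithmetic against the
# published worked values, which use the cohort-mean SV/CO directly).
mean_derived <- function(group = 1L, subject_id = "m1") {
  data.frame(
    subject_id = subject_id,
    heart_rate_bpm = 72.10, weight_kg = 74.11,
    sv_ml = 92.21, co_ml_min = 6636.71, pp_mmHg = 54.43, bsa_m2 = 1.82,
    bmi = if (group == 1L) 25.95 else 23.0,
    bmi_class = factor(if (group == 1L) "overweight" else "normal",
                       levels = c("thin", "normal", "overweight")),
    bmi_indicator = as.integer(group),
    stringsAsFactors = FALSE)
}

# Small hand-constructed cohort with varied, valid measurements.
small_cohort <- function(n = 8) {
  set.seed(424242)
  data.frame(
    subject_id = sprintf("c%02d", seq_len(n)),
    height_cm = seq(160, 180, length.out = n),
    weight_kg = seq(58, 95, length.out = n),
    heart_rate_bpm = seq(60, 85, length.out = n),
    sbp_mmHg = seq(115, 145, length.out = n),
    dbp_mmHg = seq(70, 85, length.out = n),
    lv_edd_mm = seq(45, 56, length.out = n),
    lv_esd_mm = seq(30, 38, length.out = n),
    stringsAsFactors = FALSE)
}

write_cohort_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
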