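#' Read a cohort CSV
#'
#' Expected header: `subject_id,height_cm,weight_kg,heart_rate_bpm,
#' sbp_mmHg,dbp_mmHg,lv_edd_mm,lv_esd_mm[,measured_viscosity_cp]`; UTF-8,
#' dot decimal separator, blank measured viscosity permitted. Rows that
#' fail to parse or violate a record invariant are rejected individually
#' (with their file line number) while the remaining rows load.
#'
#' @param path Path to the CSV file.
#' @return Object of class `cohort_load`: list with `subjects` (valid
#'   rows), `rejected` (data frame `line`, `subject_id`, `reason`) and
#'   `n_input`. `partial` is `TRUE` when any row was rejected.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, fileEncoding = "UTF-8")
  required <- .subject_columns
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  has_mu <- "measured_viscosity_cp" %in% names(raw)
  num_cols <- c(setdiff(required, "subject_id"),
                if (has_mu) "measured_viscosity_cp")
  n <- nrow(raw)
  parsed <- raw
  bad_parse <- rep(FALSE, n)
  parse_reason <- rep(NA_character_, n)
  for (col in num_cols) {
    v <- trimws(raw[[col]])
    blank <- v == "" | is.na(v)
    x <- suppressWarnings(as.numeric(v))
    bad <- !blank & is.na(x)
    if (col != "measured_viscosity_cp" && any(blank)) bad <- bad | blank
    newly <- bad & !bad_parse
    parse_reason[newly] <- paste0("unparseable value in column ", col)
    bad_parse <- bad_parse | bad
    parsed[[col]] <- x
  }
  if (!has_mu) parsed$measured_viscosity_cp <- NA_real_
  # file line = data row index + 1 (header line)
  rejected <- data.frame(line = which(bad_parse) + 1L,
                         subject_id = raw$subject_id[bad_parse],
                         reason = parse_reason[bad_parse],
                         stringsAsFactors = FALSE)
  ok_rows <- parsed[!bad_parse, , drop = FALSE]
  issues <- validate_subjects(ok_rows)
  if (nrow(issues)) {
    orig_line <- which(!bad_parse)[issues$row] + 1L
    rejected <- rbind(rejected, data.frame(
      line = orig_line, subject_id = issues$subject_id,
      reason = issues$reason, stringsAsFactors = FALSE))
    ok_rows <- ok_rows[-issues$row, , drop = FALSE]
  }
  rejected <- rejected[order(rejected$line), , drop = FALSE]
  rownames(ok_rows) <- NULL
  rownames(rejected) <- NULL
  structure(list(subjects = ok_rows, rejected = rejected,
                 n_input = n, partial = nrow(rejected) > 0L),
            class = "cohort_load")
}

#' @export
print.cohort_load <- function(x, ...) {
  cat(sprintf("Cohort load: %d of %d row(s) valid", nrow(x$subjects),
              x$n_input))
  if (x$partial) cat(sprintf(", %d rejected", nrow(x$rejected)))
  cat("\n")
  invisible(x)
}

#' Write a cohort (and optional ground-truth sidecar) to CSV
#'
#' @param cohort A list with `subjects` and optionally `truth` (as
#'   returned by [generate_cohort()]), or a plain subject data frame.
#' @param path Output CSV path for the subjects.
#' @param truth_path Optional output path for the ground-truth sidecar.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, truth_path = NULL) {
  subjects <- if (is.data.frame(cohort)) cohort else cohort$subjects
  keep <- intersect(c(.subject_columns, "measured_viscosity_cp"),
                    names(subjects))
  utils::write.csv(subjects[, keep, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(truth_path)) {
    if (is.data.frame(cohort) || is.null(cohort$truth)) {
      stop("no ground truth available to write")
    }
    utils::write.csv(cohort$truth, truth_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}
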