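# Delimited-text cohort I/O and packaged aggregate-count fixtures.

COHORT_COLUMNS <- c(
  "patient_id", "age", "sex", "latent_frailty",
  "Q1", "Q2", "Q3a", "Q3b", "Q4a", "Q4b", "Q5", "Q6a", "Q6b",
  "Q7", "Q8a", "Q8b", "Q9a", "Q9b",
  paste0("src_", c("Q1", "Q2", "Q3a", "Q3b", "Q4a", "Q4b", "Q5", "Q6a", "Q6b",
                   "Q7", "Q8a", "Q8b", "Q9a", "Q9b")),
  paste0("diff_", c("Q1", "Q2", "Q3a", "Q3b", "Q4a", "Q4b", "Q5", "Q6a", "Q6b",
                    "Q7", "Q8a", "Q8b", "Q9a", "Q9b")),
  "spi", "barthel", "mmse", "mna", "grip_right", "grip_left", "sppb", "clock",
  "frailty_fried", "frailty_share",
  "los_days", "nursing_minutes", "one_on_one", "mortality", "readmit_30d",
  "discharge_nh", "admitted_from_home", "completion_minutes"
)

MANDATORY_COLUMNS <- c("patient_id")

#' Read / write a cohort table
#'
#' Plain delimited text (comma by default, tab accepted), UTF-8, header
#' required. Empty fields and `"NA"` are missing markers — a zero is always
#' a value. Unknown columns are ignored with a warning; a missing mandatory
#' column (`patient_id`) is an error. `write_cohort()` then `read_cohort()`
#' reproduces the records exactly (categoricals, logicals, missing values).
#'
#' @param path File path.
#' @param sep Field separator, `","` or `"\t"`.
#' @return `read_cohort()`: a data frame of class `iceberg_cohort`.
#' @export
read_cohort <- function(path, sep = ",") {
  if (!file.exists(path)) stop_iceberg("cohort file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          na.strings = c("", "NA"), stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "")
  absent <- setdiff(MANDATORY_COLUMNS, names(df))
  if (length(absent) > 0) {
    stop_iceberg("%s: missing mandatory column(s): %s", path,
                 paste(absent, collapse = ", "))
  }
  unknown <- setdiff(names(df), COHORT_COLUMNS)
  if (length(unknown) > 0) {
    warning(sprintf("ignoring unknown column(s) in %s: %s", path,
                    paste(unknown, collapse = ", ")), call. = FALSE)
    df <- df[, setdiff(names(df), unknown), drop = FALSE]
  }
  df$patient_id <- as.character(df$patient_id)
  for (lc in c("one_on_one", "mortality", "readmit_30d", "discharge_nh",
               "admitted_from_home")) {
    if (lc %in% names(df)) df[[lc]] <- as.logical(df[[lc]])
  }
  class(df) <- c("iceberg_cohort", "data.frame")
  df
}

#' @rdname read_cohort
#' @param cohort Cohort data frame to write.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  utils::write.table(cohort, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Packaged aggregate-count fixtures from the validation pilots
#'
#' Transcriptions of the published pilot summaries: per-variable event counts
#' in the low (< 10) and high (>= 10) risk classes, and the pilot-2
#' enrollment flow. These are the inputs for the printed-count checks (the
#' patient-level pilot data were never deposited).
#'
#' @param pilot `"pilot1"` (construct-validity cohort, N = 129) or
#'   `"pilot2"` (criterion-validity cohort, N = 288).
#' @return `pilot_counts()`: data frame with columns `variable`,
#'   `events_low`, `n_low`, `events_high`, `n_high`, `provenance`.
#' @export
pilot_counts <- function(pilot = c("pilot2", "pilot1")) {
  pilot <- match.arg(pilot)
  path <- system.file("extdata", paste0(pilot, "_counts.csv"),
                      package = "icebergscreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname pilot_counts
#' @return `pilot_enrollment()`: named list with `n_consented`, `n_declined`,
#'   `n_analyzed`.
#' @export
pilot_enrollment <- function() {
  path <- system.file("extdata", "pilot2_enrollment.csv",
                      package = "icebergscreen", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as.list(stats::setNames(df$value, df$quantity))
}

#' Write a report table as delimited text and aligned text
#'
#' @param report An `iceberg_report` data frame.
#' @param csv_path,txt_path Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, csv_path = NULL, txt_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE, na = "")
  }
  if (!is.null(txt_path)) {
    lines <- utils::capture.output(print(report))
    writeLines(lines, txt_path)
  }
  invisible(report)
}
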