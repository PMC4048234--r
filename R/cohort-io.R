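# Cohort metadata table and per-islet feature tables (CSV).

COHORT_COLUMNS <- c(
  "patient_id", "group", "gender", "age", "bmi", "treatment", "source",
  "location", "n_islets_tmem27", "n_islets_bace2", "n_islets_insulin"
)
GROUP_LEVELS <- c("ND", "T2D")
GENDER_LEVELS <- c("M", "F")
SOURCE_LEVELS <- c("Surgery", "Autopsy", "Cadaveric donor")
LOCATION_LEVELS <- c("head", "body", "tail", "not specified")

check_vocab <- function(x, levels, column) {
  bad <- which(!(x %in% levels))
  if (length(bad)) {
    stop_validation(sprintf(
      "column `%s` contains value(s) outside {%s} in row(s) %s: %s",
      column, paste(levels, collapse = ", "),
      paste(head(bad, 5), collapse = ", "),
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
}

#' Load the cohort metadata table
#'
#' Reads a CSV of per-patient clinical records: diagnostic group (ND or T2D),
#' gender, age, BMI, antidiabetic treatment, tissue source and sampling
#' location, plus the number of islets pictured per stain (TMEM27, BACE2,
#' insulin). Closed vocabularies are validated row by row. A transcription of
#' the study cohort ships with the package, see the example.
#'
#' @param path CSV path with a header naming the fields `patient_id`, `group`,
#'   `gender`, `age`, `bmi`, `treatment`, `source`, `location`,
#'   `n_islets_tmem27`, `n_islets_bace2`, `n_islets_insulin`.
#' @return A tibble with one row per patient.
#' @examples
#' cohort <- load_cohort_table(
#'   system.file("extdata", "cohort_table1.csv", package = "isletscore")
#' )
#' dplyr::count(cohort, group)
#' @export
load_cohort_table <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(COHORT_COLUMNS, names(tab))
  if (length(missing)) {
    stop_format(sprintf("cohort table lacks column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  tab <- tab[COHORT_COLUMNS]
  check_vocab(tab$group, GROUP_LEVELS, "group")
  check_vocab(tab$gender, GENDER_LEVELS, "gender")
  check_vocab(tab$source, SOURCE_LEVELS, "source")
  check_vocab(tab$location, LOCATION_LEVELS, "location")
  for (col in c("n_islets_tmem27", "n_islets_bace2", "n_islets_insulin")) {
    v <- tab[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != round(v))) {
      stop_validation(sprintf("column `%s` must hold non-negative integer counts", col))
    }
    tab[[col]] <- as.integer(v)
  }
  if (!is.numeric(tab$age) || !is.numeric(tab$bmi)) {
    stop_validation("columns `age` and `bmi` must be numeric")
  }
  tab$treatment <- as.character(tab$treatment)
  tab
}

#' Write a per-islet features table
#'
#' One row per scored islet. Column order is preserved; numeric values are
#' written at full precision so a reload agrees to at least six significant
#' digits.
#'
#' @param features Non-empty data frame of per-islet features, typically rows
#'   of [tidy()][tidy.islet_score()] output plus identifying columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_table <- function(features, path) {
  if (!is.data.frame(features) || nrow(features) == 0L) {
    stop_parameter("`features` must be a data frame with at least one row")
  }
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}

#' Read a per-islet features table written by [write_features_table()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_features_table <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
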