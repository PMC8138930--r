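#' The six monitored vital signs, in canonical order
#'
#' Column order is fixed throughout the package: heart rate (HR, beats/min),
#' pulse oximetry (O2Sat, %), temperature (Temp, deg C), systolic blood
#' pressure (SBP, mm Hg), diastolic blood pressure (DBP, mm Hg) and
#' respiration rate (Resp, breaths/min).
#'
#' @return Character vector of the six column names.
#' @export
#' @examples
#' vital_signs()
vital_signs <- function() {
  c("HR", "O2Sat", "Temp", "SBP", "DBP", "Resp")
}

#' Read one patient's hourly record from a pipe-separated (.psv) file
#'
#' Files follow the hourly-ICU-record dialect: a header line of
#' pipe-separated column names, then one line per hour. Missing values are
#' the literal `NaN`; unparseable numeric cells also become missing. The
#' file must carry the six vital signs of [vital_signs()] and a binary
#' `SepsisLabel` column; any extra columns are kept as read.
#'
#' @param path Path to a `.psv` file.
#' @param patient_id Identifier for the patient; defaults to the file name
#'   without its extension.
#' @return A tibble with `patient_id`, `hour` (0-based row index) and one
#'   numeric column per header field.
#' @export
read_psv <- function(path, patient_id = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (is.null(patient_id)) {
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !nzchar(first)) {
    stop("format error: empty file ", path, call. = FALSE)
  }
  raw <- utils::read.table(
    path,
    sep = "|", header = TRUE, colClasses = "character",
    check.names = FALSE, strip.white = TRUE,
    na.strings = c("NaN", "NA", ""), comment.char = "", quote = ""
  )
  # as.numeric round-trips %.17g exactly; unparseable cells become NA
  df <- tibble::as_tibble(lapply(raw, function(x) {
    suppressWarnings(as.numeric(x))
  }))
  check_psv_columns(names(df), path)
  df |>
    dplyr::mutate(
      patient_id = patient_id,
      hour = dplyr::row_number() - 1L,
      .before = 1L
    )
}

check_psv_columns <- function(found, path = "<record>") {
  required <- c(vital_signs(), "SepsisLabel")
  missing <- setdiff(required, found)
  if (length(missing) > 0L) {
    stop(
      "format error: missing required column(s) ",
      paste(missing, collapse = ", "), " in ", path,
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Read a directory of per-patient .psv files into one cohort tibble
#'
#' @param dir Directory containing `.psv` files, one per patient.
#' @return A tibble stacking [read_psv()] output for every file, ordered by
#'   file name.
#' @export
read_psv_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.psv$", full.names = TRUE))
  if (length(files) == 0L) {
    stop("no .psv files found in ", dir, call. = FALSE)
  }
  purrr::map(files, read_psv) |> purrr::list_rbind()
}

#' Write per-patient hourly records back to .psv files
#'
#' Inverse of [read_psv()]: missing values are written as the literal
#' `NaN`, columns keep their order, and reading the file back reproduces
#' the values and missingness pattern exactly.
#'
#' @param cohort Tibble with `patient_id`, `hour` and numeric data columns.
#' @param dir Output directory (created if needed); one file
#'   `<patient_id>.psv` is written per patient.
#' @return Invisibly, the paths written.
#' @export
write_psv <- function(cohort, dir) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  paths <- cohort |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_map(function(df, key) {
      path <- file.path(dir, paste0(key$patient_id, ".psv"))
      out <- dplyr::select(df, -dplyr::any_of(c("patient_id", "hour")))
      # %.17g round-trips doubles exactly; missing cells become "NaN"
      formatted <- dplyr::mutate(out, dplyr::across(
        dplyr::where(is.numeric),
        function(x) ifelse(is.na(x), "NaN", sprintf("%.17g", x))
      ))
      readr::write_delim(formatted, path, delim = "|", progress = FALSE)
      path
    }) |>
    unlist()
  invisible(paths)
}

#' Keep only the six vital signs and the sepsis label
#'
#' Drops every other clinical variable (the source records carry 40) while
#' preserving row order and values.
#'
#' @param cohort Cohort tibble as returned by [read_psv()] /
#'   [read_psv_cohort()].
#' @return Tibble with `patient_id`, `hour`, the six vital signs and
#'   `SepsisLabel`.
#' @export
extract_vitals <- function(cohort) {
  check_psv_columns(names(cohort))
  dplyr::select(
    cohort,
    dplyr::all_of(c("patient_id", "hour", vital_signs(), "SepsisLabel"))
  )
}

#' Locate sepsis onset per patient
#'
#' Onset is the first hour whose `SepsisLabel` is 1; patients with no
#' labelled hour are negatives.
#'
#' @param cohort Tibble with `patient_id`, `hour`, `SepsisLabel`.
#' @return Tibble with one row per patient: `patient_id`, `is_positive`,
#'   `onset_index` (`NA` for negatives).
#' @export
detect_onset <- function(cohort) {
  cohort |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      is_positive = any(.data$SepsisLabel == 1, na.rm = TRUE),
      onset_index = if (any(.data$SepsisLabel == 1, na.rm = TRUE)) {
        min(.data$hour[.data$SepsisLabel == 1 & !is.na(.data$SepsisLabel)])
      } else {
        NA_integer_
      },
      .groups = "drop"
    )
}

#' Truncate positive patients at sepsis onset
#'
#' For positives the onset hour becomes the last row of the series: every
#' later register is rejected. Negatives pass through unchanged. The
#' per-row `SepsisLabel` is replaced by a per-patient `label` (1 positive,
#' 0 negative).
#'
#' @param cohort Tibble with `patient_id`, `hour`, vital-sign columns and
#'   `SepsisLabel`.
#' @return Tibble with `patient_id`, `hour`, vital signs and `label`.
#' @export
truncate_at_onset <- function(cohort) {
  onsets <- detect_onset(cohort)
  cohort |>
    dplyr::left_join(onsets, by = "patient_id") |>
    dplyr::filter(!.data$is_positive | .data$hour <= .data$onset_index) |>
    dplyr::mutate(label = as.integer(.data$is_positive)) |>
    dplyr::select(-dplyr::all_of(c("SepsisLabel", "is_positive", "onset_index")))
}
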