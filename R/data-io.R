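#' Validate a corticosterone sample table
#'
#' Checks a table of individual bird records against the constraints the
#' downstream gamma-likelihood models assume: strictly positive CORT
#' (gamma support), non-negative sampling times, baseline bleeds taken in
#' under 3 minutes, trapping-confinement times inside the study window
#' (10--210 min), unique bird identifiers, and known treatment / sex codes.
#'
#' @param data A data frame with columns `bird_id`, `treatment`
#'   (`"shot"`, `"baseline"`, `"trapped"`), `sex` (`"female"`, `"male"`,
#'   `"unknown"`), `time_min` (minutes since net activation; 0 by convention
#'   for shot birds) and `cort_ng_ml` (plasma corticosterone, ng/ml).
#' @param strict If `TRUE` (default) any invalid row aborts with
#'   row-indexed messages; if `FALSE` invalid rows are dropped with warnings.
#' @param validate_windows If `TRUE` (default) enforce the study-design time
#'   windows (baseline < 3 min, trapped within \[10, 210\] min). Set `FALSE`
#'   for data from other sampling designs.
#'
#' @return A validated tibble with the five canonical columns.
#' @export
#' @examples
#' df <- tibble::tibble(
#'   bird_id = c("b1", "b2"), treatment = c("baseline", "trapped"),
#'   sex = c("female", "male"), time_min = c(2, 45), cort_ng_ml = c(4.1, 38)
#' )
#' validate_cort_data(df)
validate_cort_data <- function(data, strict = TRUE, validate_windows = TRUE) {
  missing <- setdiff(cort_columns, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)[cort_columns]

  msgs <- character()
  bad <- rep(FALSE, nrow(data))
  flag <- function(idx, text) {
    if (any(idx, na.rm = TRUE)) {
      rows <- which(idx)
      msgs <<- c(msgs, paste0("row ", rows, ": ", text))
      bad[rows] <<- TRUE
    }
  }

  flag(!data$treatment %in% treatment_levels,
       "treatment must be one of shot, baseline, trapped")
  flag(!data$sex %in% sex_levels, "sex must be one of female, male, unknown")
  flag(!is.finite(data$cort_ng_ml),
       "cort_ng_ml must be a finite number")
  flag(is.finite(data$cort_ng_ml) & data$cort_ng_ml <= 0,
       "cort_ng_ml must be > 0 (gamma support)")
  flag(!is.finite(data$time_min), "time_min must be a finite number")
  flag(is.finite(data$time_min) & data$time_min < 0,
       "time_min must be >= 0")
  if (validate_windows) {
    flag(data$treatment == "baseline" & is.finite(data$time_min) &
           data$time_min >= 3,
         "baseline samples must be drawn < 3 minutes after capture")
    flag(data$treatment == "trapped" & is.finite(data$time_min) &
           (data$time_min < 10 | data$time_min > 210),
         "trapped samples must lie within [10, 210] minutes")
  }
  flag(duplicated(data$bird_id), "duplicate bird_id (each bird sampled once)")

  if (length(msgs) > 0) {
    if (strict) {
      abort(c("invalid corticosterone records:", msgs))
    }
    warn(c("dropping invalid corticosterone records:", msgs))
    data <- data[!bad, , drop = FALSE]
  }
  data
}

#' Read a corticosterone sample table from CSV
#'
#' Reads a comma-delimited, UTF-8 table with header columns `bird_id`,
#' `treatment`, `sex`, `time_min`, `cort_ng_ml` and validates it with
#' [validate_cort_data()].
#'
#' @param path Path to the CSV file.
#' @inheritParams validate_cort_data
#' @return A validated tibble of samples; the source path is recorded in the
#'   `"provenance"` attribute.
#' @export
read_cort_data <- function(path, strict = TRUE, validate_windows = TRUE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      bird_id = readr::col_character(),
      treatment = readr::col_character(),
      sex = readr::col_character(),
      time_min = readr::col_double(),
      cort_ng_ml = readr::col_double(),
      .default = readr::col_skip()
    )
  )
  out <- validate_cort_data(raw, strict = strict,
                            validate_windows = validate_windows)
  attr(out, "provenance") <- path
  out
}

#' Write a corticosterone sample table to CSV
#'
#' Writes the five canonical columns comma-delimited with full numeric
#' precision, so that `read_cort_data(write_cort_data(x, p))` round-trips to
#' an identical table.
#'
#' @param data A data frame of samples (see [validate_cort_data()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cort_data <- function(data, path) {
  data <- validate_cort_data(data, strict = TRUE, validate_windows = FALSE)
  readr::write_csv(data, path)
  invisible(path)
}

#' Summarise CORT by treatment group
#'
#' Ordinary sample statistics per treatment: group size, mean, standard
#' deviation (n - 1 denominator) and standard error of the mean. Because
#' published "mean +/- spread" values are not always labelled SD or SE, both
#' are reported.
#'
#' @param data A data frame of samples with `treatment` and `cort_ng_ml`.
#' @return A tibble with one row per treatment present, ordered
#'   shot / baseline / trapped, and columns `treatment`, `n`, `mean_cort`,
#'   `sd_cort`, `se_cort`.
#' @export
#' @examples
#' summarize_groups(simulate_cort_data())
summarize_groups <- function(data) {
  if (nrow(data) == 0) abort("cannot summarise an empty dataset")
  data |>
    dplyr::mutate(treatment = factor(.data$treatment,
                                     levels = treatment_levels)) |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_cort = mean(.data$cort_ng_ml),
      sd_cort = sd(.data$cort_ng_ml),
      se_cort = sd(.data$cort_ng_ml) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$treatment) |>
    dplyr::mutate(treatment = as.character(.data$treatment))
}
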