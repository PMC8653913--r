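#' Read an ambulatory EDA recording from delimited text
#'
#' Reads a CSV with header `t,eda[,temp,accel_x,accel_y,accel_z]`.  `t` is
#' either seconds since recording start (numeric) or ISO-8601 timestamps
#' (auto-detected and converted to elapsed seconds from the first sample).
#' `eda` is skin conductance in microsiemens.
#'
#' @param path Path to a CSV file.
#' @param sample_rate Nominal sampling rate in Hz. If `NULL` (default) it is
#'   estimated as the reciprocal of the median sample spacing.
#' @return An `eda_recording`: a tibble with columns `t` (seconds) and `eda`
#'   (microsiemens), plus any extra channels present, carrying a
#'   `sample_rate` attribute.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write.csv(data.frame(t = (0:19) / 4, eda = 2 + sin(0:19 / 4)), path,
#'           row.names = FALSE)
#' rec <- read_recording(path)
#' attr(rec, "sample_rate")
read_recording <- function(path, sample_rate = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("t", "eda") %in% names(df))) {
    stop_edapeaks("recording must have columns `t` and `eda`",
                  "edapeaks_input_error")
  }
  if (inherits(df$t, "POSIXct")) {
    df$t <- as.numeric(df$t) - as.numeric(df$t[1])
  } else if (is.character(df$t)) {
    tt <- as.POSIXct(df$t, tz = "UTC", tryFormats = c(
      "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    df$t <- as.numeric(tt) - as.numeric(tt[1])
  }
  as_recording(df, sample_rate = sample_rate)
}

#' Construct an EDA recording from a data frame
#'
#' @param df Data frame with numeric columns `t` (seconds, strictly
#'   increasing) and `eda` (microsiemens); optional extra channels.
#' @inheritParams read_recording
#' @return An `eda_recording` tibble.
#' @export
as_recording <- function(df, sample_rate = NULL) {
  df <- tibble::as_tibble(df)
  if (!all(c("t", "eda") %in% names(df))) {
    stop_edapeaks("recording must have columns `t` and `eda`",
                  "edapeaks_input_error")
  }
  if (is.unsorted(df$t, strictly = TRUE)) {
    stop_edapeaks("recording timestamps must be strictly increasing",
                  "edapeaks_input_error")
  }
  if (!all(is.finite(df$eda))) {
    stop_edapeaks("skin-conductance values must all be finite",
                  "edapeaks_input_error")
  }
  if (is.null(sample_rate)) {
    sample_rate <- 1 / median(diff(df$t))
  }
  if (!is_number(sample_rate) || sample_rate <= 0) {
    stop_edapeaks("sample_rate must be a positive number",
                  "edapeaks_input_error")
  }
  new_eda_tbl(df, "eda_recording", sample_rate = sample_rate)
}

#' Read task-window definitions
#'
#' Accepts CSV with columns `participant_id,assessment_id,task_id,start,end`
#' (seconds relative to the recording start) or an equivalent JSON array of
#' objects.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return A tibble of task windows, validated (end > start, no overlap
#'   within a participant/assessment).
#' @export
read_task_windows <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  as_task_windows(df)
}

#' @rdname read_task_windows
#' @param df Data frame of task windows.
#' @export
as_task_windows <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("task_id", "start", "end")
  if (!all(need %in% names(df))) {
    stop_edapeaks("task windows need columns task_id, start, end",
                  "edapeaks_input_error")
  }
  if (!"participant_id" %in% names(df)) df$participant_id <- "p1"
  if (!"assessment_id" %in% names(df)) df$assessment_id <- "a1"
  if (any(df$end <= df$start)) {
    stop_edapeaks("every task window must have end > start",
                  "edapeaks_input_error")
  }
  overlap <- df |>
    dplyr::group_by(.data$participant_id, .data$assessment_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(
      bad = any(head(.data$end, -1) > tail(.data$start, -1) + 1e-9),
      .groups = "drop")
  if (any(overlap$bad)) {
    stop_edapeaks("task windows overlap within a participant/assessment",
                  "edapeaks_input_error")
  }
  df[, union(c("participant_id", "assessment_id", "task_id", "start", "end"),
             names(df))]
}
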