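#' Extract one task segment on an elapsed-time axis
#'
#' Cuts the samples falling in `[start, end)` of a task window out of a
#' recording and re-expresses their times as seconds elapsed since the task
#' start, so profiles from different participants and assessments share a
#' common time scale.  Transmission gaps inside the window are retained as
#' gaps (no interpolation).
#'
#' @param recording An `eda_recording` (see [as_recording()]).
#' @param window A one-row data frame or list with at least `task_id`,
#'   `start`, `end` (seconds); optionally `participant_id`, `assessment_id`.
#' @return An `eda_segment`: tibble with `elapsed` (s), `eda` (microsiemens)
#'   and any extra channels; attributes `window` and `sample_rate`.
#' @export
#' @examples
#' rec <- as_recording(data.frame(t = (0:2399) / 4,
#'                                eda = 2 + 0.2 * sin((0:2399) / 40)))
#' seg <- segment_by_window(rec, list(task_id = "stroop", start = 100, end = 400))
#' range(seg$elapsed)
segment_by_window <- function(recording, window) {
  window <- as.list(window)
  stopifnot(!is.null(window$start), !is.null(window$end))
  keep <- recording$t >= window$start & recording$t < window$end
  if (!any(keep)) {
    stop_edapeaks(
      sprintf("window [%g, %g) ('%s') does not overlap the recording",
              window$start, window$end, window$task_id %||% "?"),
      "edapeaks_empty_segment")
  }
  seg <- recording[keep, , drop = FALSE]
  seg <- dplyr::mutate(seg, elapsed = .data$t - window$start,
                       .before = 1L)
  new_eda_tbl(tibble::as_tibble(seg), "eda_segment",
              window = window,
              sample_rate = attr(recording, "sample_rate", exact = TRUE))
}

#' Flag near-zero (loose-connection) samples as invalid
#'
#' Skin-conductance values that are approximately zero indicate that the dry
#' electrodes lost contact with the skin; such samples are flagged invalid.
#' The default threshold is 0.05 microsiemens, the exclusion rule established
#' for ambulatory EDA.  The same mask applies to raw and filtered variants of
#' a segment, since flagging is based on the measured conductance.
#'
#' @param segment An `eda_segment` (or any tibble with an `eda` column).
#' @param near_zero_threshold Threshold in microsiemens; samples with
#'   `eda < near_zero_threshold` are flagged `near_zero`.
#' @return The segment with added columns `valid` (logical) and `reason`
#'   (`"valid"` or `"near_zero"`).  If every sample is invalid a warning of
#'   class `edapeaks_all_invalid` is signalled and the segment is still
#'   returned so batch callers can record the failure.  On a filtered
#'   segment the mask is computed from the retained raw channel
#'   (`eda_raw`), so raw and filtered pipelines always flag the same
#'   sample indices.
#' @export
flag_invalid <- function(segment, near_zero_threshold = 0.05) {
  stopifnot(is_number(near_zero_threshold), near_zero_threshold > 0)
  sc <- if ("eda_raw" %in% names(segment)) segment$eda_raw else segment$eda
  out <- dplyr::mutate(
    segment,
    valid = sc >= near_zero_threshold,
    reason = ifelse(.data$valid, "valid", "near_zero"))
  attr(out, "near_zero_threshold") <- near_zero_threshold
  if (!any(out$valid)) {
    rlang::warn(sprintf("all %d samples flagged near_zero; segment unusable",
                        nrow(out)),
                class = "edapeaks_all_invalid")
  }
  out
}

#' Remove invalid samples, preserving the elapsed-time axis
#'
#' Near-zero runs are excised rather than zero-filled: the surviving samples
#' keep their original elapsed times, yielding unequally spaced data that the
#' smoothing methods tolerate.
#'
#' @param segment Output of [flag_invalid()].
#' @return The segment restricted to valid samples (error of class
#'   `edapeaks_all_invalid` if none survive).
#' @export
excise_invalid <- function(segment) {
  if (!"valid" %in% names(segment)) {
    stop_edapeaks("run flag_invalid() before excise_invalid()",
                  "edapeaks_input_error")
  }
  out <- segment[segment$valid, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop_edapeaks("all samples are invalid (near_zero); nothing to analyse",
                  "edapeaks_all_invalid")
  }
  n_flagged <- sum(!segment$valid)
  attr(out, "n_excised") <- n_flagged
  out
}

#' Normalize an EDA task segment to [0, 1]
#'
#' Rescales skin conductance within one task segment by the range and the
#' distance from the maximum:
#' \deqn{x' = 1 - \frac{\max - x}{\max - \min}}
#' so the segment minimum maps to 0 and the maximum to 1.  This puts
#' participants and assessments with very different conductance ranges on a
#' common scale before smoothing.  Computed over valid samples of this
#' segment only; run [flag_invalid()] / [excise_invalid()] first if the
#' segment may contain loose-connection samples.
#'
#' @param segment An `eda_segment` with columns `elapsed` and `eda`.
#' @param source Label recorded on the profile: `"raw"` or `"filtered"`.
#' @return An `eda_profile`: tibble with `elapsed` (s) and `value` (unitless
#'   in \[0, 1\]), attributes `min_eda`, `max_eda` (microsiemens), `source`.
#' @export
#' @examples
#' seg <- tibble::tibble(elapsed = 0:2, eda = c(2, 3, 4))
#' normalize_eda(seg)$value  # 0, 0.5, 1
normalize_eda <- function(segment, source = c("raw", "filtered")) {
  source <- rlang::arg_match(source)
  if ("valid" %in% names(segment)) segment <- segment[segment$valid, ]
  if (nrow(segment) < 2L) {
    stop_edapeaks("need at least 2 valid samples to normalize",
                  "edapeaks_too_short")
  }
  mx <- max(segment$eda)
  mn <- min(segment$eda)
  if (mx <= mn) {
    stop_edapeaks(
      sprintf("degenerate range: max == min == %g microsiemens", mx),
      "edapeaks_degenerate_range")
  }
  out <- tibble::tibble(elapsed = segment$elapsed,
                        value = 1 - (mx - segment$eda) / (mx - mn))
  new_eda_tbl(out, "eda_profile",
              min_eda = mn, max_eda = mx, source = source,
              sample_rate = attr(segment, "sample_rate", exact = TRUE),
              window = attr(segment, "window", exact = TRUE))
}
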