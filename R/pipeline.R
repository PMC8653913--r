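#' Pipeline configuration
#'
#' Validated bag of every tunable parameter in the processing chain, with
#' documented defaults.  Serializes to/from YAML via [read_pipeline_config()];
#' unknown keys are rejected.
#'
#' @param filter `"fir"` to low-pass filter before normalization, `"none"`
#'   to work on the raw conductance.
#' @param cutoff FIR cutoff frequency, Hz (default 0.5).
#' @param n_taps FIR tap count; `NULL` means 4 x sample rate (16 at 4 Hz).
#' @param near_zero Invalid-sample threshold, microsiemens (default 0.05).
#' @param methods Smoothers to run: any of `"fda"`, `"lpr"` (default both,
#'   so their fits can be compared per profile).
#' @param n_basis `"auto"` or a fixed basis size for the spline smoother.
#' @param lambda `"auto"` or a fixed roughness penalty.
#' @param degree Local polynomial degree (default 1).
#' @param d_max Maximum AR order (default 8).
#' @param grid_factor Evaluation-grid density multiple (default 10).
#' @param peak_threshold Drop threshold for peak identification
#'   (default 0.1).
#' @param seed Integer seed recorded with the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(filter = c("fir", "none"),
                            cutoff = 0.5,
                            n_taps = NULL,
                            near_zero = 0.05,
                            methods = c("fda", "lpr"),
                            n_basis = "auto",
                            lambda = "auto",
                            degree = 1L,
                            d_max = 8L,
                            grid_factor = 10,
                            peak_threshold = 0.1,
                            seed = NULL) {
  filter <- rlang::arg_match(filter)
  methods <- match.arg(methods, c("fda", "lpr"), several.ok = TRUE)
  stopifnot(is_number(near_zero), near_zero > 0,
            is_number(peak_threshold), peak_threshold > 0,
            is_number(grid_factor), grid_factor >= 1)
  structure(list(filter = filter, cutoff = cutoff, n_taps = n_taps,
                 near_zero = near_zero, methods = methods,
                 n_basis = n_basis, lambda = lambda,
                 degree = as.integer(degree), d_max = as.integer(d_max),
                 grid_factor = grid_factor,
                 peak_threshold = peak_threshold, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys are [pipeline_config()]
#'   arguments; unknown keys are an error.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop_edapeaks(paste0("unknown config key(s): ",
                         paste(bad, collapse = ", ")),
                  "edapeaks_config_error")
  }
  do.call(pipeline_config, vals)
}

#' Run the full EDA feature pipeline over a batch of task windows
#'
#' For every participant x assessment x task window and every configured
#' smoothing method: segment, optionally FIR-filter, flag and excise
#' near-zero samples, normalize, smooth, identify peaks, and compute the
#' feature row.  Per-profile failures (all-invalid, degenerate range, too
#' short) are caught and reported in a failures table without aborting the
#' batch, and sample counts at every stage are logged on each feature row.
#'
#' @param recordings A single `eda_recording`, or a named list of them
#'   keyed by `participant_id`.
#' @param windows A task-window tibble (see [read_task_windows()]).
#' @param config A [pipeline_config()].
#' @return A list of class `eda_pipeline_result`:
#'   `features` (one row per profile per method, with stage sample counts),
#'   `failures` (`participant_id`, `assessment_id`, `task_id`, `method`,
#'   `reason`, `message`), `profiles` and `peaks` (named lists keyed by
#'   `participant.assessment.task.method`), and `config`.
#' @export
run_pipeline <- function(recordings, windows, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(recordings, "eda_recording")) {
    recordings <- setNames(list(recordings),
                           windows$participant_id[1] %||% "p1")
  }
  windows <- as_task_windows(windows)
  features <- list(); failures <- list()
  profiles <- list(); peaks_out <- list()
  for (r in seq_len(nrow(windows))) {
    w <- windows[r, ]
    rec <- recordings[[as.character(w$participant_id)]]
    if (is.null(rec)) {
      failures[[length(failures) + 1L]] <- fail_row(
        w, NA_character_, "missing_recording",
        sprintf("no recording for participant '%s'", w$participant_id))
      next
    }
    for (method in config$methods) {
      key <- paste(w$participant_id, w$assessment_id, w$task_id, method,
                   sep = ".")
      res <- tryCatch(
        process_profile(rec, w, config, method),
        edapeaks_error = function(e) e,
        edapeaks_all_invalid = function(e) e)
      if (inherits(res, "condition")) {
        failures[[length(failures) + 1L]] <- fail_row(
          w, method, failure_reason(res), conditionMessage(res))
      } else {
        features[[length(features) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(participant_id = w$participant_id,
                         assessment_id = w$assessment_id,
                         task_id = w$task_id, method = method),
          res$features,
          tibble::tibble(n_read = res$n_read, n_flagged = res$n_flagged,
                         n_excised = res$n_excised, n_fit = res$n_fit))
        profiles[[key]] <- res$smooth
        peaks_out[[key]] <- res$peaks
      }
    }
  }
  structure(list(
    features = dplyr::bind_rows(features),
    failures = if (length(failures)) dplyr::bind_rows(failures) else
      tibble::tibble(participant_id = character(0),
                     assessment_id = character(0), task_id = character(0),
                     method = character(0), reason = character(0),
                     message = character(0)),
    profiles = profiles, peaks = peaks_out, config = config),
    class = "eda_pipeline_result")
}

fail_row <- function(w, method, reason, message) {
  tibble::tibble(participant_id = as.character(w$participant_id),
                 assessment_id = as.character(w$assessment_id),
                 task_id = as.character(w$task_id),
                 method = method, reason = reason, message = message)
}

failure_reason <- function(cond) {
  cls <- class(cond)
  if ("edapeaks_all_invalid" %in% cls) return("near_zero")
  if ("edapeaks_degenerate_range" %in% cls) return("degenerate_range")
  if ("edapeaks_too_short" %in% cls) return("too_short")
  if ("edapeaks_empty_segment" %in% cls) return("empty_segment")
  cls[1]
}

process_profile <- function(rec, w, config, method) {
  seg <- segment_by_window(rec, w)
  n_read <- nrow(seg)
  if (config$filter == "fir") {
    sr <- attr(seg, "sample_rate", exact = TRUE)
    taps <- config$n_taps %||% round(4 * sr)
    filt <- design_fir_lowpass(sr, cutoff = config$cutoff, n_taps = taps)
    seg <- apply_fir(seg, filt)
  }
  flagged <- withCallingHandlers(
    flag_invalid(seg, config$near_zero),
    edapeaks_all_invalid = function(w_) invokeRestart("muffleWarning"))
  n_flagged <- sum(!flagged$valid)
  if (n_flagged == nrow(flagged)) {
    stop_edapeaks(sprintf("all %d samples near zero; segment unusable",
                          n_flagged), "edapeaks_all_invalid")
  }
  valid <- excise_invalid(flagged)
  prof <- normalize_eda(valid,
                        source = if (config$filter == "fir") "filtered"
                        else "raw")
  sm <- if (method == "fda") {
    smooth_fda(prof, n_basis = config$n_basis, lambda = config$lambda,
               grid_factor = config$grid_factor)
  } else {
    fit_lpr_ar(prof, degree = config$degree, d_max = config$d_max,
               grid_factor = config$grid_factor)
  }
  pk <- find_peaks(sm, threshold = config$peak_threshold)
  list(features = compute_features(pk, sm),
       smooth = sm, peaks = pk,
       n_read = n_read, n_flagged = n_flagged,
       n_excised = n_flagged, n_fit = nrow(prof))
}

#' Write pipeline outputs to a directory
#'
#' Writes `features.csv`, `failures.csv`, one `profile_<key>.csv`
#' (`t,value,d1,d2`) and `peaks_<key>.json` per successful profile, and a
#' `run_log.csv` of per-stage sample counts.  Missing feature values are
#' empty fields in CSV and `null` in JSON.
#'
#' @param result An `eda_pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "eda_pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$features, file.path(dir, "features.csv"), na = "")
  readr::write_csv(result$failures, file.path(dir, "failures.csv"), na = "")
  for (key in names(result$profiles)) {
    readr::write_csv(result$profiles[[key]],
                     file.path(dir, paste0("profile_", key, ".csv")))
    jsonlite::write_json(
      result$peaks[[key]],
      file.path(dir, paste0("peaks_", key, ".json")),
      dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA)
  }
  log_cols <- intersect(c("participant_id", "assessment_id", "task_id",
                          "method", "n_read", "n_flagged", "n_excised",
                          "n_fit"), names(result$features))
  readr::write_csv(result$features[, log_cols],
                   file.path(dir, "run_log.csv"), na = "")
  invisible(dir)
}
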