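#' Plot an EDA recording
#'
#' @param object An `eda_recording`.
#' @param ... Unused.
#' @return A ggplot: skin conductance against time.
#' @method autoplot eda_recording
#' @export
autoplot.eda_recording <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$eda)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Skin conductance (µS)") +
    ggplot2::theme_minimal()
}

#' Plot a smoothed EDA profile
#'
#' Smoothed curve, optionally overlaying the normalized samples it was
#' fitted to.
#'
#' @param object An `eda_smooth`.
#' @param profile Optional `eda_profile` of the underlying samples.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eda_smooth
#' @export
autoplot.eda_smooth <- function(object, profile = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$value))
  if (!is.null(profile)) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(t = profile$elapsed, value = profile$value),
      colour = "grey60", size = 0.4)
  }
  p + ggplot2::geom_line(colour = "#2166ac", linewidth = 0.7) +
    ggplot2::labs(x = "Elapsed task time (s)", y = "Normalized EDA",
                  title = paste0("Smoothed profile (",
                                 meta_of(object)$method, ")")) +
    ggplot2::theme_minimal()
}

#' Plot identified peaks on their smoothed profile
#'
#' The smoothed curve with vertical markers at every identified apex: the
#' first peak, the highest peak, and all others distinguished by colour,
#' matching the conventional presentation of EDA peak features.
#'
#' @param object An `eda_peaks` (with its source profile attached, as
#'   produced by [find_peaks()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eda_peaks
#' @export
autoplot.eda_peaks <- function(object, ...) {
  prof <- attr(object, "profile", exact = TRUE)
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = "Elapsed task time (s)", y = "Normalized EDA") +
    ggplot2::theme_minimal()
  if (nrow(object)) {
    pk <- dplyr::arrange(tibble::as_tibble(object), .data$t_apex)
    role <- rep("other", nrow(pk))
    role[1] <- "first"
    role[which.max(pk$v_apex)] <- "highest"
    pk$role <- role
    p <- p +
      ggplot2::geom_vline(data = pk,
                          ggplot2::aes(xintercept = .data$t_apex,
                                       colour = .data$role),
                          linetype = "dashed") +
      ggplot2::geom_point(data = pk,
                          ggplot2::aes(x = .data$t_apex, y = .data$v_apex,
                                       colour = .data$role), size = 2) +
      ggplot2::scale_colour_manual(
        values = c(first = "red", highest = "black", other = "blue"),
        name = "Peak")
  }
  p
}

#' Plot the features table of a pipeline run
#'
#' Peak counts by task and method — a quick overview of a batch run.
#'
#' @param result An `eda_pipeline_result`.
#' @return A ggplot.
#' @export
plot_feature_summary <- function(result) {
  ggplot2::ggplot(result$features,
                  ggplot2::aes(x = .data$task_id, y = .data$n_peaks,
                               fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ .data$participant_id + .data$assessment_id) +
    ggplot2::labs(x = "Task", y = "Identified peaks") +
    ggplot2::theme_minimal()
}
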