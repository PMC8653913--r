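#' Locate candidate extrema of a smoothed EDA profile
#'
#' Local maxima are points where the first derivative crosses zero from
#' positive to negative with negative second derivative; minima are the
#' opposite crossings.  Crossing times are refined by linear interpolation
#' of the first derivative between the bracketing grid points, and the
#' curve value at the refined time is interpolated likewise.  The segment
#' endpoints are registered as boundary extrema so drop computations at the
#' edges are explicit.
#'
#' @param profile An `eda_smooth` (columns `t`, `value`, `d1`, `d2`).
#' @return A tibble with columns `t`, `value`, `type` (`"max"`/`"min"`),
#'   `boundary` (logical), sorted by `t`; carries the profile as attribute
#'   `profile`.
#' @export
find_extrema <- function(profile) {
  stopifnot(all(c("t", "value", "d1", "d2") %in% names(profile)))
  t <- profile$t; v <- profile$value
  d1 <- profile$d1; d2 <- profile$d2
  n <- length(t)
  rows <- list()
  if (n >= 2L) {
    i <- which(d1[-n] > 0 & d1[-1L] <= 0)  # + to - : maximum
    j <- which(d1[-n] < 0 & d1[-1L] >= 0)  # - to + : minimum
    # refine each bracketed d1 zero crossing: cubic Hermite interpolation
    # of d1 on [t_k, t_{k+1}] (using d2 = d1 slope at the ends), root by
    # bisection, then Hermite interpolation of the curve value there
    interp_at <- function(k) {
      refine <- function(kk) {
        t0 <- t[kk]; t1 <- t[kk + 1L]
        hseg <- t1 - t0
        f0 <- d1[kk]; f1 <- d1[kk + 1L]
        g0 <- d2[kk] * hseg; g1 <- d2[kk + 1L] * hseg
        herm <- function(s, y0, y1, m0, m1) {
          (2 * s^3 - 3 * s^2 + 1) * y0 + (s^3 - 2 * s^2 + s) * m0 +
            (-2 * s^3 + 3 * s^2) * y1 + (s^3 - s^2) * m1
        }
        lo <- 0; hi <- 1
        if (!is.finite(f0) || !is.finite(f1) || f0 == f1) return(t0)
        flo <- f0
        for (it in 1:40) {
          mid <- (lo + hi) / 2
          fm <- herm(mid, f0, f1, g0, g1)
          if (is.na(fm) || fm == 0) break
          if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
        }
        s <- (lo + hi) / 2
        t0 + s * hseg
      }
      tc <- vapply(k, refine, numeric(1))
      s <- (tc - t[k]) / (t[k + 1L] - t[k])
      hseg <- t[k + 1L] - t[k]
      hval <- (2 * s^3 - 3 * s^2 + 1) * v[k] +
        (s^3 - 2 * s^2 + s) * d1[k] * hseg +
        (-2 * s^3 + 3 * s^2) * v[k + 1L] +
        (s^3 - s^2) * d1[k + 1L] * hseg
      list(t = tc,
           value = hval,
           d2 = d2[k] + s * (d2[k + 1L] - d2[k]))
    }
    if (length(i)) {
      mx <- interp_at(i)
      keep <- mx$d2 < 0
      rows$mx <- tibble::tibble(t = mx$t[keep], value = mx$value[keep],
                                type = "max", boundary = FALSE)
    }
    if (length(j)) {
      # minima are all - to + crossings; no curvature condition, so kink
      # minima (e.g. a new phasic event starting on a decaying tail) count
      mn <- interp_at(j)
      rows$mn <- tibble::tibble(t = mn$t, value = mn$value,
                                type = "min", boundary = FALSE)
    }
  }
  rows$edges <- tibble::tibble(
    t = c(t[1], t[n]),
    value = c(v[1], v[n]),
    type = c(if (!is.na(d1[1]) && d1[1] < 0) "max" else "min",
             if (!is.na(d1[n]) && d1[n] > 0) "max" else "min"),
    boundary = TRUE)
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$t)
  attr(out, "profile") <- profile
  out
}

#' Filter candidate maxima into peaks by their side drops
#'
#' For every interior candidate maximum the nearest local minimum on each
#' side determines a left and a right drop (apex value minus minimum
#' value).  The maximum is a peak only if both drops exceed the threshold
#' (default 0.1 on the normalized scale).  A maximum whose right side runs
#' into the end of the profile without a local minimum is an incomplete
#' peak and is discarded regardless of its drops; at the left edge the
#' segment start value may serve as the left minimum and is flagged.
#'
#' @param candidates Extrema tibble from [find_extrema()].
#' @param threshold Minimum drop on each side, normalized EDA units
#'   (default 0.1).
#' @param left_edge_as_min If `TRUE` (default) the profile start value can
#'   act as a left minimum (flagged `left_is_edge`); if `FALSE` peaks with
#'   no interior left minimum are discarded symmetrically to the right
#'   rule.
#' @return An `eda_peaks` tibble: one row per peak with `t_apex`, `v_apex`,
#'   `t_left_min`, `v_left_min`, `t_right_min`, `v_right_min`,
#'   `drop_left`, `drop_right`, `left_is_edge`.
#' @export
filter_peaks <- function(candidates, threshold = 0.1,
                         left_edge_as_min = TRUE) {
  stopifnot(is_number(threshold), threshold > 0)
  cand <- dplyr::arrange(candidates, .data$t)
  maxima <- cand[cand$type == "max" & !cand$boundary, , drop = FALSE]
  minima <- cand[cand$type == "min", , drop = FALSE]
  res <- purrr::map(seq_len(nrow(maxima)), function(i) {
    ta <- maxima$t[i]; va <- maxima$value[i]
    left <- minima[minima$t < ta, , drop = FALSE]
    right <- minima[minima$t > ta & !minima$boundary, , drop = FALSE]
    # incomplete peak at the right limit: no interior minimum follows
    if (nrow(right) == 0L) return(NULL)
    rmin <- right[1L, ]
    left_is_edge <- FALSE
    if (nrow(left) == 0L) return(NULL)
    lmin <- left[nrow(left), ]
    if (lmin$boundary) {
      if (!left_edge_as_min) return(NULL)
      left_is_edge <- TRUE
    }
    tibble::tibble(
      t_apex = ta, v_apex = va,
      t_left_min = lmin$t, v_left_min = lmin$value,
      t_right_min = rmin$t, v_right_min = rmin$value,
      drop_left = va - lmin$value, drop_right = va - rmin$value,
      left_is_edge = left_is_edge)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      t_apex = numeric(0), v_apex = numeric(0),
      t_left_min = numeric(0), v_left_min = numeric(0),
      t_right_min = numeric(0), v_right_min = numeric(0),
      drop_left = numeric(0), drop_right = numeric(0),
      left_is_edge = logical(0))
  } else {
    out <- out[out$drop_left > threshold & out$drop_right > threshold, ,
               drop = FALSE]
  }
  new_eda_tbl(out, "eda_peaks",
              threshold = threshold,
              profile = attr(candidates, "profile", exact = TRUE))
}

#' Identify peaks on a smoothed EDA profile
#'
#' Convenience wrapper: [find_extrema()] then [filter_peaks()].
#'
#' @param profile An `eda_smooth`.
#' @inheritParams filter_peaks
#' @return An `eda_peaks` tibble.
#' @export
#' @examples
#' sim <- eda_scenario("clean", seed = 1)
#' seg <- segment_by_window(sim$recording,
#'                          list(task_id = "task", start = 0, end = 300))
#' prof <- normalize_eda(flag_invalid(seg) |> excise_invalid())
#' pk <- find_peaks(smooth_fda(prof))
#' nrow(pk)
find_peaks <- function(profile, threshold = 0.1, left_edge_as_min = TRUE) {
  filter_peaks(find_extrema(profile), threshold = threshold,
               left_edge_as_min = left_edge_as_min)
}

#' Per-profile peak features
#'
#' Summarises a set of identified peaks into the feature row used for
#' statistical modelling: the number of peaks, time to the first and to the
#' highest peak, amplitudes at both, reactivity (time from the highest apex
#' to its right minimum, i.e. how fast the signal returns toward baseline),
#' the drop from the highest peak, and the trapezoidal area under the whole
#' smoothed curve.  AUC is reported together with the segment duration
#' because differing observed time spans make raw AUC hard to compare
#' across individuals.  Ties on the highest amplitude resolve to the
#' earliest apex.
#'
#' @param peaks An `eda_peaks` tibble (may be empty).
#' @param profile The `eda_smooth` the peaks came from; defaults to the one
#'   attached to `peaks`.
#' @return A one-row tibble with columns `n_peaks`, `t_first_peak`,
#'   `t_highest_peak`, `amp_first_peak`, `amp_highest_peak`,
#'   `reactivity_s`, `drop_highest`, `auc`, `duration_s`.  All peak-derived
#'   fields are `NA` when no peaks exist.
#' @export
compute_features <- function(peaks, profile = attr(peaks, "profile")) {
  auc <- NA_real_; dur <- NA_real_
  if (!is.null(profile)) {
    tt <- profile$t; vv <- profile$value
    auc <- sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2)
    dur <- tt[length(tt)] - tt[1]
  }
  if (nrow(peaks) == 0L) {
    return(tibble::tibble(
      n_peaks = 0L, t_first_peak = NA_real_, t_highest_peak = NA_real_,
      amp_first_peak = NA_real_, amp_highest_peak = NA_real_,
      reactivity_s = NA_real_, drop_highest = NA_real_,
      auc = auc, duration_s = dur))
  }
  pk <- dplyr::arrange(peaks, .data$t_apex)
  hi <- which.max(pk$v_apex)  # first index on ties = earliest apex
  tibble::tibble(
    n_peaks = nrow(pk),
    t_first_peak = pk$t_apex[1],
    t_highest_peak = pk$t_apex[hi],
    amp_first_peak = pk$v_apex[1],
    amp_highest_peak = pk$v_apex[hi],
    reactivity_s = pk$t_right_min[hi] - pk$t_apex[hi],
    drop_highest = pk$drop_right[hi],
    auc = auc,
    duration_s = dur)
}
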