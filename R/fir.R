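#' Design an FIR low-pass filter for EDA denoising
#'
#' Windowed-sinc (Hamming) linear-phase low-pass design via [signal::fir1()],
#' with coefficients normalized to unit DC gain so the tonic skin-conductance
#' level passes unchanged.  The default tap count is four times the sample
#' rate (16 taps at 4 Hz).
#'
#' @param sample_rate Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz; must lie strictly below the Nyquist
#'   frequency `sample_rate / 2`.  Default 0.5 Hz: phasic
#'   skin-conductance-response energy lies well below this at 4 Hz sampling.
#' @param n_taps Number of filter coefficients (default `4 * sample_rate`).
#' @return An object of class `fir_filter`: list with `coefficients`,
#'   `n_taps`, `cutoff`, `sample_rate`.
#' @export
#' @examples
#' f <- design_fir_lowpass(4)
#' length(f$coefficients)  # 16
#' sum(f$coefficients)     # 1
design_fir_lowpass <- function(sample_rate, cutoff = 0.5,
                               n_taps = round(4 * sample_rate)) {
  stopifnot(is_number(sample_rate), sample_rate > 0, is_number(n_taps))
  n_taps <- as.integer(n_taps)
  if (n_taps < 2L) {
    stop_edapeaks("n_taps must be at least 2", "edapeaks_parameter_error")
  }
  if (!is_number(cutoff) || cutoff <= 0 || cutoff >= sample_rate / 2) {
    stop_edapeaks(
      sprintf("cutoff must lie in (0, %g) Hz (below Nyquist)", sample_rate / 2),
      "edapeaks_parameter_error")
  }
  h <- as.numeric(signal::fir1(n_taps - 1L, cutoff / (sample_rate / 2),
                               type = "low"))
  h <- h / sum(h)
  structure(list(coefficients = h, n_taps = n_taps, cutoff = cutoff,
                 sample_rate = sample_rate),
            class = "fir_filter")
}

#' Magnitude response of an FIR filter
#'
#' Direct discrete-frequency evaluation of the transfer function.
#'
#' @param filter A `fir_filter`.
#' @param freq Frequencies in Hz.
#' @return Numeric vector of magnitude gains (unitless).
#' @export
fir_response <- function(filter, freq) {
  k <- seq_along(filter$coefficients) - 1L
  vapply(freq, function(f) {
    Mod(sum(filter$coefficients * exp(-2i * pi * f * k / filter$sample_rate)))
  }, numeric(1))
}

#' Apply an FIR low-pass filter to a task segment
#'
#' Convolves the skin-conductance channel with the filter, compensating the
#' linear-phase group delay of `(n_taps - 1) / 2` samples so peaks keep
#' their original times.  For an even tap count the delay is half-integral
#' and is removed exactly by averaging the two straddling convolution
#' samples (a half-sample linear-phase interpolator).  Edges are padded by
#' replication, and samples whose filtered value depends on the padding are
#' flagged `transient`.
#'
#' @param segment An `eda_segment` with at least `elapsed` and `eda`.
#' @param filter A `fir_filter` from [design_fir_lowpass()].
#' @return The segment with `eda` replaced by the filtered signal, the
#'   original retained as `eda_raw`, and a logical `transient` column.
#' @export
apply_fir <- function(segment, filter) {
  stopifnot(inherits(filter, "fir_filter"))
  x <- segment$eda
  n <- length(x)
  p <- filter$n_taps
  if (n <= p) {
    stop_edapeaks(
      sprintf("segment (%d samples) must be longer than the filter (%d taps)",
              n, p),
      "edapeaks_too_short")
  }
  pad <- p
  xp <- c(rep(x[1], pad), x, rep(x[n], pad))
  f <- as.numeric(stats::filter(xp, filter$coefficients,
                                method = "convolution", sides = 1))
  delay <- (p - 1) / 2
  idx <- pad + seq_len(n) + floor(delay)
  if (delay %% 1 == 0) {
    y <- f[idx]
  } else {
    y <- (f[idx] + f[idx + 1L]) / 2
  }
  half <- ceiling(delay)
  out <- dplyr::mutate(segment,
                       eda_raw = .data$eda,
                       eda = y,
                       transient = dplyr::row_number() <= half |
                         dplyr::row_number() > dplyr::n() - half)
  attr(out, "fir_filter") <- filter
  out
}
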