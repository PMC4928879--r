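#' Discrete signal container
#'
#' A minimal container for one channel's evenly sampled time series: a numeric
#' vector of values plus its sampling rate in Hz. Gaps (missing motion-capture
#' samples) are represented as `NA`; EMG channels must be gap-free.
#'
#' @param values numeric vector of samples. `NA` marks a gap.
#' @param rate sampling rate in Hz (positive scalar).
#' @return An object of class `emg_signal` with elements `values`, `rate`
#'   and `n` (length).
#' @examples
#' s <- emg_signal(sin(seq(0, 2 * pi, length.out = 100)), rate = 100)
#' @export
emg_signal <- function(values, rate) {
  if (!is.numeric(values) || length(values) < 1L)
    stop("'values' must be a non-empty numeric vector")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("'rate' must be a positive scalar (Hz)")
  structure(list(values = as.numeric(values), rate = as.numeric(rate),
                 n = length(values)),
            class = "emg_signal")
}

#' @export
print.emg_signal <- function(x, ...) {
  cat(sprintf("<emg_signal> %d samples @ %g Hz (%.3f s), %d gap(s)\n",
              x$n, x$rate, x$n / x$rate, sum(is.na(x$values))))
  invisible(x)
}

as_signal <- function(x, rate) {
  if (inherits(x, "emg_signal")) x else emg_signal(x, rate)
}

#' Full-wave rectification
#'
#' Replaces every sample by its absolute value. Length and rate are preserved;
#' the operation is idempotent.
#'
#' @param signal an [emg_signal].
#' @return rectified [emg_signal].
#' @export
rectify <- function(signal) {
  stopifnot(inherits(signal, "emg_signal"))
  emg_signal(abs(signal$values), signal$rate)
}

# Zero-phase IIR filtering with reflection padding. A forward and a backward
# pass cancel the phase; the effective magnitude response is the square of a
# single pass. Pad length is sized to let the filter transient decay well
# below 1e-9 before the retained segment begins.
zero_phase_filter <- function(values, filt, pad) {
  n <- length(values)
  pad <- min(n - 1L, as.integer(pad))
  if (pad > 0L) {
    # reflect about the end points so a constant stays exactly constant
    head_pad <- 2 * values[1L] - values[seq(pad + 1L, 2L)]
    tail_pad <- 2 * values[n] - values[seq(n - 1L, n - pad)]
    x <- c(head_pad, values, tail_pad)
  } else {
    x <- values
  }
  y <- signal::filter(filt, x)
  y <- rev(signal::filter(filt, rev(y)))
  if (pad > 0L) y <- y[seq(pad + 1L, pad + n)]
  as.numeric(y)
}

#' Butterworth low-pass filter
#'
#' Low-pass filters a signal with a Butterworth design of the given order.
#' By default the filter is applied zero-phase (forward-backward), so peak
#' timing is not shifted; the magnitude response is then the square of a
#' single pass (half-power point at the cutoff becomes an amplitude ratio of
#' 0.5). DC gain is 1 in either mode.
#'
#' @param signal an [emg_signal] without gaps.
#' @param order filter order (single pass), >= 1.
#' @param cutoff cutoff frequency in Hz; must lie below the Nyquist frequency.
#' @param zero_phase apply forward-backward (default `TRUE`); `FALSE` gives a
#'   single causal pass.
#' @return filtered [emg_signal] of the same length and rate.
#' @export
butterworth_lowpass <- function(signal, order = 4L, cutoff, zero_phase = TRUE) {
  stopifnot(inherits(signal, "emg_signal"))
  if (anyNA(signal$values))
    stop("signal contains gaps; interpolate before filtering")
  if (order < 1L) stop("'order' must be >= 1")
  nyq <- signal$rate / 2
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= nyq)
    stop(sprintf("'cutoff' must lie in (0, %g) Hz (Nyquist)", nyq))
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  pad <- ceiling(10 * signal$rate / cutoff) + 20L * order
  y <- if (zero_phase) {
    zero_phase_filter(signal$values, bf, pad)
  } else {
    n <- length(signal$values)
    p <- min(n - 1L, as.integer(pad))
    x <- if (p > 0L) c(2 * signal$values[1L] - signal$values[seq(p + 1L, 2L)],
                       signal$values) else signal$values
    as.numeric(signal::filter(bf, x))[if (p > 0L) seq(p + 1L, p + n) else seq_len(n)]
  }
  emg_signal(y, signal$rate)
}

#' Reduce the sampling rate with anti-alias filtering
#'
#' Applies a zero-phase Butterworth anti-alias low-pass (cutoff 0.4 x the
#' target rate, i.e. 0.8 x the target Nyquist; order 4 per pass, giving an
#' 8th-order magnitude roll-off) and then resamples onto the target time grid
#' by linear interpolation. The output has `floor(n * target_rate / rate)`
#' samples. Works for non-integer rate ratios such as 4000 -> 120 Hz.
#'
#' @param signal an [emg_signal] without gaps.
#' @param target_rate desired rate in Hz, strictly below `signal$rate`.
#' @param antialias_order Butterworth order of the single-pass anti-alias
#'   filter (default 4).
#' @return decimated [emg_signal] at `target_rate`.
#' @export
decimate <- function(signal, target_rate, antialias_order = 4L) {
  stopifnot(inherits(signal, "emg_signal"))
  if (anyNA(signal$values))
    stop("signal contains gaps; interpolate before decimating")
  if (!is.numeric(target_rate) || target_rate <= 0 || target_rate >= signal$rate)
    stop("'target_rate' must be positive and below the input rate")
  cutoff <- 0.4 * target_rate
  filtered <- butterworth_lowpass(signal, order = antialias_order,
                                  cutoff = cutoff, zero_phase = TRUE)
  n_out <- floor(signal$n * target_rate / signal$rate)
  if (n_out < 1L) stop("signal too short for the requested target rate")
  t_in <- (seq_len(signal$n) - 1) / signal$rate
  t_out <- (seq_len(n_out) - 1) / target_rate
  y <- stats::approx(t_in, filtered$values, xout = t_out, rule = 2)$y
  emg_signal(y, target_rate)
}

#' Fill interior gaps by linear interpolation
#'
#' Motion-capture streams can drop samples; gaps are carried as `NA`. Interior
#' gaps are filled linearly between the neighbouring observed samples; leading
#' and trailing gaps are trimmed (the returned signal may be shorter).
#' Non-gap samples are never modified.
#'
#' @param signal an [emg_signal], possibly with `NA` gaps.
#' @return gap-free [emg_signal].
#' @export
interpolate_gaps <- function(signal) {
  stopifnot(inherits(signal, "emg_signal"))
  v <- signal$values
  ok <- which(!is.na(v))
  if (length(ok) == 0L) stop("signal consists entirely of gaps")
  v <- v[ok[1L]:ok[length(ok)]]
  if (anyNA(v)) {
    idx <- seq_along(v)
    obs <- !is.na(v)
    v[!obs] <- stats::approx(idx[obs], v[obs], xout = idx[!obs])$y
  }
  emg_signal(v, signal$rate)
}

#' Standard EMG preprocessing chain
#'
#' Rectification, rate reduction to `target_rate` with anti-alias filtering,
#' then a Butterworth low-pass (default 4th order, 20 Hz) to obtain a smooth
#' activation envelope.
#'
#' @param signal raw EMG [emg_signal].
#' @param target_rate output rate in Hz (default 120).
#' @param cutoff envelope low-pass cutoff in Hz (default 20).
#' @param order envelope filter order (default 4).
#' @param zero_phase zero-phase filtering (default `TRUE`).
#' @return preprocessed [emg_signal] at `target_rate`.
#' @export
preprocess_emg <- function(signal, target_rate = 120, cutoff = 20, order = 4L,
                           zero_phase = TRUE) {
  s <- rectify(signal)
  s <- decimate(s, target_rate)
  butterworth_lowpass(s, order = order, cutoff = cutoff, zero_phase = zero_phase)
}

#' Standard kinematics preprocessing chain
#'
#' Gap interpolation followed by a Butterworth low-pass (default 4th order,
#' 10 Hz) of the marker trajectory.
#'
#' @param signal marker-coordinate [emg_signal], gaps allowed.
#' @param cutoff low-pass cutoff in Hz (default 10).
#' @param order filter order (default 4).
#' @param zero_phase zero-phase filtering (default `TRUE`).
#' @return filtered gap-free [emg_signal].
#' @export
preprocess_kinematics <- function(signal, cutoff = 10, order = 4L,
                                  zero_phase = TRUE) {
  s <- interpolate_gaps(signal)
  butterworth_lowpass(s, order = order, cutoff = cutoff, zero_phase = zero_phase)
}
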