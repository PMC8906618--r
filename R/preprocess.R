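#' Filter specification
#'
#' The pipeline default reproduces the reference processing chain: a 6th
#' order low-pass Butterworth filter with cutoff 20 Hz, applied forward and
#' backward (zero phase lag).  An "ideal" FFT brick-wall low-pass is
#' available as a comparison utility; it is not part of the default
#' pipeline because hard spectral truncation introduces endpoint artefacts.
#'
#' @param cutoff_hz Cutoff frequency fc in Hz; must lie below the Nyquist
#'   frequency of the series it is applied to.
#' @param order Butterworth order of the single-pass design (even, >= 2).
#'   Forward-backward application squares the magnitude response, i.e.
#'   doubles the effective attenuation order.
#' @param kind `"butterworth_zero_lag"` or `"ideal_fft"`.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(cutoff_hz = 20, order = 6,
                        kind = c("butterworth_zero_lag", "ideal_fft")) {
  kind <- match.arg(kind)
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0)
    stop("cutoff_hz must be positive")
  if (kind == "butterworth_zero_lag" &&
      (order < 2 || order %% 2 != 0))
    stop("Butterworth order must be an even integer >= 2")
  structure(list(cutoff_hz = cutoff_hz, order = as.integer(order),
                 kind = kind), class = "filter_spec")
}

#' Remove (and report) a least-squares linear trend
#'
#' Non-harmonic drift is removed before filtering by fitting a straight
#' line to the series and subtracting it; after filtering the trend is
#' re-added, so detrend + trend reconstructs the input exactly.
#'
#' @param x Numeric series (>= 2 finite samples).
#' @return List with `detrended` and `trend` (both same length as `x`);
#'   `detrended + trend == x`.
#' @export
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to fit a trend")
  ok <- is.finite(x)
  if (sum(ok) < 2L) stop("series has fewer than 2 finite samples")
  t <- seq_len(n)
  cf <- stats::lm.fit(cbind(1, t[ok]), x[ok])$coefficients
  trend <- cf[1] + cf[2] * t
  list(detrended = x - trend, trend = trend)
}

# Odd-symmetric reflection padding: continues the series through its
# endpoints, suppressing start-up transients of the zero-state filter.
reflect_pad <- function(x, p) {
  n <- length(x)
  p <- min(p, n - 1L)
  if (p <= 0L) return(list(x = x, p = 0L))
  head_pad <- 2 * x[1] - x[(p + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - p)]
  list(x = c(head_pad, x, tail_pad), p = p)
}

#' Zero-lag Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass forward and then backward
#' (filtfilt), cancelling the phase delay.  Edges are handled by
#' odd-reflection padding (default one tenth of the series length, at
#' least 120 samples -- about one stride at typical capture rates) so
#' endpoint transients of the zero-state filter do not reach the data.
#'
#' @param x Numeric series (finite).
#' @param spec A [filter_spec()] with `kind = "butterworth_zero_lag"`.
#' @param frame_rate Sampling frequency in Hz.
#' @param pad Padding length in samples (`NULL` = automatic).
#' @return Filtered series, same length as `x`; DC gain is 1 and the output
#'   has zero phase shift relative to the input.
#' @export
butterworth_zero_lag <- function(x, spec = filter_spec(), frame_rate,
                                 pad = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$kind != "butterworth_zero_lag")
    stop("spec$kind must be \"butterworth_zero_lag\"")
  if (spec$cutoff_hz >= frame_rate / 2)
    stop("cutoff (", spec$cutoff_hz, " Hz) must be below the Nyquist frequency (",
         frame_rate / 2, " Hz)")
  if (!all(is.finite(x))) stop("series must be finite (fill gaps first)")
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  bf <- signal::butter(spec$order, spec$cutoff_hz / (frame_rate / 2),
                       type = "low")
  if (is.null(pad)) pad <- max(120L, ceiling(n / 10))
  padded <- reflect_pad(x, pad)
  y <- signal::filter(bf, padded$x)
  y <- rev(signal::filter(bf, rev(as.numeric(y))))
  as.numeric(y)[(padded$p + 1):(padded$p + n)]
}

#' Ideal (brick-wall) FFT low-pass filter
#'
#' Transforms the series to the frequency domain, zeroes every bin whose
#' frequency magnitude exceeds the cutoff (both conjugate halves), and
#' transforms back.  Retained as a comparison utility: energy above the
#' cutoff is exactly zero by construction, but the hard truncation can ring
#' near the series endpoints.
#'
#' @inheritParams butterworth_zero_lag
#' @param spec A [filter_spec()] with `kind = "ideal_fft"`.
#' @return Filtered (real) series, same length as `x`.
#' @export
ideal_lowpass_fft <- function(x, spec, frame_rate) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$kind != "ideal_fft") stop("spec$kind must be \"ideal_fft\"")
  # a brick wall at the Nyquist frequency keeps every bin (all-pass)
  if (spec$cutoff_hz > frame_rate / 2)
    stop("cutoff must not exceed the Nyquist frequency")
  if (!all(is.finite(x))) stop("series must be finite (fill gaps first)")
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  freq <- (seq_len(n) - 1L) / n * frame_rate
  freq <- pmin(freq, frame_rate - freq)  # magnitude frequency per bin
  spec_x <- stats::fft(x)
  spec_x[freq > spec$cutoff_hz] <- 0+0i
  Re(stats::fft(spec_x, inverse = TRUE)) / n
}

#' Filter every marker component of a recording
#'
#' Each of the 75 marker-coordinate components is independently linearly
#' detrended, low-pass filtered and re-trended.  Interior dropout gaps are
#' linearly interpolated before filtering so the filter sees a finite
#' series; the missing-sample mask is left unchanged, so downstream
#' consumers still know which samples were interpolated.  Markers with no
#' observed samples are passed through untouched.
#'
#' @param rec A [trial_recording()].
#' @param spec A [filter_spec()]; default 6th order Butterworth, fc = 20 Hz.
#' @return The filtered `trial_recording`.
#' @export
filter_trial <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "trial_recording"))
  markers <- dimnames(rec$positions)[[3]]
  for (m in markers) {
    if (!any(rec$mask[, m])) next
    for (ax in c("x", "y", "z")) {
      v <- rec$positions[, ax, m]
      v[!rec$mask[, m]] <- NA_real_
      v <- fill_gaps(v)
      dt <- detrend_linear(v)
      f <- switch(spec$kind,
                  butterworth_zero_lag =
                    butterworth_zero_lag(dt$detrended, spec, rec$frame_rate),
                  ideal_fft =
                    ideal_lowpass_fft(dt$detrended, spec, rec$frame_rate))
      rec$positions[, ax, m] <- f + dt$trend
    }
  }
  rec
}
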