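#' Slow-time variance of every range bin
#'
#' For each range bin j the statistic is the unnormalised sum of squared
#' deviations of its slow-time samples from their mean within the analysis
#' window.  Normalisation is omitted on purpose: only the argmax across
#' bins matters, and dropping the 1/N factor keeps the statistic exactly as
#' the selection rule uses it.
#'
#' @param R A `radar_matrix` (rows = range bins, columns = slow time).
#' @param window_length Number of slow-time samples in the analysis window
#'   (default 2048, or the whole record, with a warning, when fewer samples
#'   exist).  An explicit window longer than the record is an error.
#' @param window_offset 1-based slow-time index where the window starts.
#' @return Tibble with columns `bin`, `variance`; attributes
#'   `window_length`, `window_offset`.
#' @export
bin_variances <- function(R, window_length = NULL, window_offset = 1L) {
  N <- ncol(R)
  if (is.null(window_length)) {
    window_length <- min(2048L, N)
    if (N < 2048L) {
      warn(sprintf("record has %d slow-time samples (< 2048); using the whole record as one window", N))
    }
  } else if (window_length > N) {
    abort("`window_length` exceeds the number of slow-time samples")
  }
  if (window_offset < 1 || window_offset + window_length - 1 > N) {
    abort("analysis window does not fit within the record")
  }
  X <- unclass(R)[, window_offset:(window_offset + window_length - 1), drop = FALSE]
  v <- rowSums((X - rowMeans(X))^2)
  structure(
    tibble(bin = seq_len(nrow(R)), variance = v),
    window_length = window_length, window_offset = window_offset
  )
}

#' Select the candidate range bin
#'
#' Picks the range bin with the largest slow-time variance; ties break to
#' the lowest index.  A profile that is identically zero means nothing in
#' the scene moved.
#'
#' @param profile Output of [bin_variances()], or a `radar_matrix` (the
#'   profile is then computed with default window settings).
#' @return Integer range-bin index (1-based).
#' @export
select_candidate_bin <- function(profile) {
  if (inherits(profile, "radar_matrix")) profile <- bin_variances(profile)
  v <- profile$variance
  if (length(v) == 0) abort("empty variance profile")
  if (any(v < 0)) abort("variances must be non-negative")
  if (all(v == 0)) abort("no motion detected")
  which.max(v)  # ties -> lowest index
}

#' Extract and band-limit a slow-time signal from one range bin
#'
#' Takes the chosen bin's slow-time row, removes its mean (static clutter
#' appears as a DC offset), and applies a zero-phase low-pass filter that
#' keeps the respiration band.  The filter is realised as a real gain on
#' the spectrum of the mirror-extended signal: unity up to `cutoff`, a
#' raised-cosine roll-off over `transition`, zero beyond — exactly zero
#' phase, so instantaneous-frequency estimates downstream see no group
#' delay.
#'
#' @param R A `radar_matrix`.
#' @param bin Range-bin index; default: [select_candidate_bin()] on `R`.
#' @param cutoff Low-pass edge, Hz (default 0.7 Hz, i.e. 42 breaths/min).
#' @param transition Width of the roll-off above `cutoff`, Hz.
#' @return Tibble with `time`, `value`; attributes `rate`, `origin_bin`.
#' @export
extract_slow_time <- function(R, bin = NULL, cutoff = 0.7, transition = 0.2) {
  rate <- attr(R, "slow_rate")
  bin <- bin %||% select_candidate_bin(R)
  if (bin < 1 || bin > nrow(R)) abort("invalid range-bin index")
  if (cutoff <= 0 || cutoff >= rate / 2) abort("`cutoff` must lie in (0, rate/2)")
  x <- as.numeric(unclass(R)[bin, ])
  x <- x - mean(x)
  y <- lowpass_zero_phase(x, rate, cutoff, transition)
  structure(
    tibble(time = (seq_along(y) - 1) / rate, value = y),
    rate = rate, origin_bin = bin, cutoff = cutoff
  )
}

#' Zero-phase FFT low-pass filter
#'
#' Applies a purely real frequency-domain gain (no phase distortion by
#' construction): 1 below `cutoff`, raised-cosine to 0 across
#' `(cutoff, cutoff + transition)`, 0 above.  The signal is mirror-extended
#' before the transform to suppress wrap-around edge artefacts and trimmed
#' afterwards.
#'
#' @param x Numeric signal.
#' @param rate Sampling rate, Hz.
#' @param cutoff Passband edge, Hz.
#' @param transition Roll-off width, Hz.  The default keeps the stopband
#'   close to the nominal respiration band edge, so broadband noise just
#'   above the band cannot capture a decomposition mode.
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_zero_phase <- function(x, rate, cutoff = 0.7, transition = 0.2) {
  ext <- mirror_extend(x)
  f <- ext$values
  n <- length(f)
  freq <- (seq_len(n) - 1) / n * rate
  freq <- pmin(freq, rate - freq)     # two-sided |frequency|
  gain <- numeric(n)
  gain[freq <= cutoff] <- 1
  ramp <- freq > cutoff & freq < cutoff + transition
  gain[ramp] <- 0.5 * (1 + cos(pi * (freq[ramp] - cutoff) / transition))
  y <- Re(stats::fft(stats::fft(f) * gain, inverse = TRUE) / n)
  y[ext$start:ext$end]
}
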