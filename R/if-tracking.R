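#' Instantaneous frequency of a narrowband mode
#'
#' Forms the analytic signal via the FFT Hilbert transform — with both
#' record ends continued by a phase-coherent AR(2) linear prediction
#' (tapered to zero, then trimmed) so the circular transform sees no edge
#' discontinuity — and differentiates the phase: centred differences in
#' the interior, one-sided at the ends, computed wrap-free as
#' `Arg(z[i+1] * Conj(z[i-1])) / 2`.  Output is clipped to the physical
#' band `[0, rate/2]`.
#'
#' @param mode Real narrowband signal (e.g. one VMD mode), length >= 8.
#' @param rate Sampling rate, Hz.
#' @return Instantaneous-frequency series in Hz, same length as `mode`.
#' @examples
#' t <- seq(0, 50, by = 1 / 152.6)
#' f <- instantaneous_frequency(sin(2 * pi * 0.2 * t), 152.6)
#' @export
instantaneous_frequency <- function(mode, rate) {
  n <- length(mode)
  if (n < 8) abort("mode too short for instantaneous-frequency estimation")
  if (all(mode == 0)) abort("empty mode")
  z <- analytic_extend(mode)
  dphi <- numeric(n)
  dphi[2:(n - 1)] <- Arg(z[3:n] * Conj(z[1:(n - 2)])) / 2
  dphi[1] <- Arg(z[2] * Conj(z[1]))
  dphi[n] <- Arg(z[n] * Conj(z[n - 1]))
  pmin(pmax(dphi * rate / (2 * pi), 0), rate / 2)
}

#' Dominant oscillatory period of a mode
#'
#' The reciprocal of the mode's centre frequency.  The rate-smoothing
#' window is three times this period.
#'
#' @param center_frequency Centre frequency in Hz (> 0).
#' @return List with `period_s` (`1 / f`) and `window_s` (`3 / f`).
#' @export
dominant_period <- function(center_frequency) {
  if (!is.numeric(center_frequency) || center_frequency <= 0) {
    abort("`center_frequency` must be positive")
  }
  list(period_s = 1 / center_frequency, window_s = 3 / center_frequency)
}

#' Smooth an instantaneous-frequency trace
#'
#' Centred moving average with a rectangular window of width `window_s`
#' seconds (height 1); edge windows are truncated and renormalised, and NA
#' samples (e.g. gated-out breath holds) are excluded from their windows.
#' A constant trace is a fixed point.
#'
#' @param raw_if Raw instantaneous-frequency series, Hz.
#' @param rate Sampling rate, Hz.
#' @param window_s Window width in seconds (>= `2 / rate`).
#' @return Smoothed series, same length.
#' @export
smooth_if <- function(raw_if, rate, window_s) {
  if (window_s < 2 / rate) abort("`window_s` must be at least two samples wide")
  w <- max(1L, round(window_s * rate))
  if (w %% 2 == 0) w <- w + 1L          # symmetric window
  moving_average(raw_if, w)
}

#' Low-amplitude gating of a respiration mode
#'
#' A mode segment whose amplitude envelope falls below a fraction
#' (default 25%) of the target's normal breathing amplitude is not a
#' usable respiration signal (e.g. a breath hold) and is masked out.  The
#' envelope is the magnitude of the analytic signal smoothed over one
#' dominant period; the reference amplitude defaults to the median
#' envelope over the most active third of the record.
#'
#' @param mode Real mode signal.
#' @param rate Sampling rate, Hz.
#' @param center_frequency Mode centre frequency, Hz (sets the envelope
#'   smoothing span).
#' @param reference Reference ("normal breathing") amplitude; default as
#'   described above.
#' @param threshold Fraction of `reference` below which samples are
#'   invalid.
#' @return Logical vector, `TRUE` where the mode is a valid respiration
#'   signal.
#' @export
gate_low_amplitude <- function(mode, rate, center_frequency,
                               reference = NULL, threshold = 0.25) {
  env <- Mod(analytic_extend(mode))
  env <- moving_average(env, round(rate / center_frequency))
  if (is.null(reference)) {
    hi <- stats::quantile(env, 2 / 3, names = FALSE)
    reference <- stats::median(env[env >= hi])
  }
  if (reference <= 0) abort("`reference` amplitude must be positive")
  env >= threshold * reference
}

#' Track per-target respiration rates from a decomposition
#'
#' For each selected respiration mode: estimate the raw instantaneous
#' frequency, gate out low-amplitude (breath-hold) segments, and smooth
#' with a rectangular window three dominant periods wide.  Gated-out
#' samples are reported as `NA` with `valid = FALSE`.
#'
#' @param object A [vmd()] result.
#' @param modes Mode indices to track; default
#'   [select_respiration_modes()] with `band` and `energy_fraction`.
#' @param band,energy_fraction Passed to [select_respiration_modes()].
#' @param gate_threshold Envelope fraction for [gate_low_amplitude()].
#' @param reference_amplitude Optional fixed gating reference.
#' @return An `if_tracks` tibble: `time`, `mode`, `center_frequency_hz`,
#'   `if_raw_hz`, `if_smoothed_hz`, `rate_bpm` (`60 *` smoothed), `valid`;
#'   attribute `window_s` (named per mode).
#' @export
track_rates <- function(object, modes = NULL, band = c(0.1, 0.7),
                        energy_fraction = 0.05, gate_threshold = 0.25,
                        reference_amplitude = NULL) {
  stopifnot(inherits(object, "vmd"))
  modes <- modes %||% select_respiration_modes(object, band, energy_fraction)
  if (length(modes) == 0) {
    return(structure(
      tibble(time = numeric(), mode = integer(),
             center_frequency_hz = numeric(), if_raw_hz = numeric(),
             if_smoothed_hz = numeric(), rate_bpm = numeric(),
             valid = logical()),
      window_s = numeric(), class = c("if_tracks", class(tibble()))
    ))
  }
  rate <- object$rate
  t <- (seq_len(nrow(object$modes)) - 1) / rate
  windows <- numeric(length(modes))
  out <- purrr::imap_dfr(modes, function(m, i) {
    mode <- object$modes[, m]
    omega <- object$center_frequencies[m]
    raw <- instantaneous_frequency(mode, rate)
    valid <- gate_low_amplitude(mode, rate, omega,
                                reference = reference_amplitude,
                                threshold = gate_threshold)
    gated <- ifelse(valid, raw, NA_real_)
    win <- dominant_period(omega)$window_s
    windows[i] <<- win
    smoothed <- smooth_if(gated, rate, win)
    smoothed[!valid] <- NA_real_
    tibble(
      time = t, mode = as.integer(m), center_frequency_hz = omega,
      if_raw_hz = gated, if_smoothed_hz = smoothed,
      rate_bpm = 60 * smoothed, valid = valid
    )
  })
  structure(out, window_s = stats::setNames(windows, modes),
            class = c("if_tracks", class(out)))
}

#' Plot respiration-rate tracks
#'
#' @param object An `if_tracks` tibble from [track_rates()].
#' @param bpm Plot breaths/min (default) rather than Hz.
#' @param ... Unused.
#' @export
autoplot.if_tracks <- function(object, bpm = TRUE, ...) {
  df <- dplyr::filter(object, .data$valid)
  y <- if (bpm) "rate_bpm" else "if_smoothed_hz"
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data[[y]],
                                   colour = factor(.data$mode))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)",
                  y = if (bpm) "respiration rate (breaths/min)"
                      else "respiration rate (Hz)",
                  colour = "mode")
}
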