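#' Describe one breathing target
#'
#' A target is a stationary reflector at standoff distance `distance_m`
#' whose chest moves sinusoidally: `x_i(t) = a_i(t) sin(phi_i(t))` with
#' phase `phi_i(t) = 2 pi \int f_i(u) du`, so that a constant rate schedule
#' reduces to the plain sinusoid `a_i sin(2 pi f_i t)` while ramps and
#' piecewise schedules are supported through the integral.
#'
#' @param distance_m Standoff distance from the radar, metres (> 0).
#' @param rate Breathing-rate schedule in Hz: a single number (constant
#'   rate), a two-column data frame with columns `time_s` and `rate_hz`
#'   (piecewise-linear interpolation, held constant beyond the last break),
#'   or a function of time returning Hz.  Values must lie in \[0, 1\] Hz.
#' @param amplitude_m Peak chest displacement, metres (default 5 mm, a
#'   typical adult tidal excursion).
#' @param reflect Dimensionless reflection amplitude `A_i` of the echo
#'   (wall attenuation is folded into this scalar).
#' @param amplitude_schedule Optional dimensionless envelope on the
#'   breathing amplitude: a data frame with columns `time_s` and `value`
#'   (piecewise-linear) or a function of time; used e.g. for breath-holding
#'   episodes.  Default: constant 1.
#' @param label Optional target name used in messages and ground truth.
#'
#' @return A `target_spec` object (a validated list).
#' @examples
#' target_spec(1.5, rate = 0.2)
#' target_spec(1.5, rate = data.frame(time_s = c(0, 30), rate_hz = c(0.2, 0.3)))
#' @export
target_spec <- function(distance_m, rate, amplitude_m = 0.005, reflect = 1,
                        amplitude_schedule = NULL, label = NULL) {
  if (!is.numeric(distance_m) || length(distance_m) != 1 || distance_m <= 0) {
    abort("`distance_m` must be a single positive number")
  }
  if (!is.numeric(amplitude_m) || amplitude_m < 0) {
    abort("`amplitude_m` must be >= 0")
  }
  sched <- as_schedule(rate, what = "rate")
  rng <- schedule_range(sched)
  if (rng[1] < 0 || rng[2] > 1) {
    abort("rate schedule values must lie within [0, 1] Hz")
  }
  structure(
    list(
      distance_m = distance_m,
      amplitude_m = amplitude_m,
      reflect = reflect,
      rate_schedule = sched,
      amplitude_schedule = if (is.null(amplitude_schedule)) NULL
                           else as_schedule(amplitude_schedule, what = "value"),
      label = label
    ),
    class = "target_spec"
  )
}

# normalise a schedule (number, data frame, or function) into a function of t
as_schedule <- function(x, what = "rate") {
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 1) {
    force(x)
    return(function(t) rep(x, length(t)))
  }
  if (is.data.frame(x)) {
    ycol <- intersect(c("rate_hz", "value"), names(x))
    if (!("time_s" %in% names(x)) || length(ycol) == 0) {
      abort(paste0("a schedule data frame needs columns `time_s` and `",
                   if (what == "rate") "rate_hz" else "value", "`"))
    }
    tt <- x$time_s
    yy <- x[[ycol[1]]]
    return(function(t) stats::approx(tt, yy, xout = t, rule = 2)$y)
  }
  abort("schedule must be a number, a data frame, or a function")
}

schedule_range <- function(sched, horizon = 600) {
  vals <- sched(seq(0, horizon, by = 0.5))
  range(vals)
}

#' Radar sampling configuration
#'
#' Defaults mirror a single-channel UWB impulse radar digitising 512 range
#' bins at a 39 GHz fast-time (intra-pulse) rate while pulses repeat at a
#' 152.6 Hz slow-time rate.  Range-bin spacing is `c_mps / (2 * fast_rate)`
#' (about 3.8 mm at the defaults).
#'
#' @param slow_rate Slow-time (pulse-to-pulse) sampling rate, Hz.
#' @param fast_rate Fast-time sampling rate within each echo, Hz.
#' @param n_bins Number of range bins J per echo.
#' @param n_slow Number of slow-time samples N (default 50 s of data).
#' @param pulse_scale Width parameter (seconds) of the first-derivative
#'   Gaussian transmit pulse.  The default places the -10 dB amplitude band
#'   at roughly 0.85-9.55 GHz.
#' @param c_mps Propagation speed, m/s.
#' @return A `radar_config` list.
#' @export
radar_config <- function(slow_rate = 152.6, fast_rate = 39e9, n_bins = 512,
                         n_slow = 7630, pulse_scale = 3.674e-11,
                         c_mps = 2.998e8) {
  stopifnot(slow_rate > 0, fast_rate > 0, n_bins >= 2, n_slow >= 2,
            pulse_scale > 0, c_mps > 0)
  structure(
    list(slow_rate = slow_rate, fast_rate = fast_rate, n_bins = n_bins,
         n_slow = n_slow, pulse_scale = pulse_scale, c_mps = c_mps,
         bin_spacing_m = c_mps / (2 * fast_rate)),
    class = "radar_config"
  )
}

#' Static clutter and noise specification
#'
#' The wall and other static reflectors are modelled as a fixed random
#' fast-time profile repeated across slow time; receiver and environment
#' noise as i.i.d. white Gaussian samples scaled so that the echo component
#' (targets only) has the requested signal-to-noise ratio.
#'
#' @param amplitude Standard deviation of the static clutter profile
#'   (0 disables clutter).
#' @param snr_db Signal-to-noise ratio of the target echo versus the added
#'   white noise, in dB.  `Inf` (default) disables noise.
#' @param seed Integer seed making clutter and noise reproducible.
#' @return A `clutter_spec` list.
#' @export
clutter_spec <- function(amplitude = 0, snr_db = Inf, seed = NULL) {
  stopifnot(amplitude >= 0)
  structure(list(amplitude = amplitude, snr_db = snr_db, seed = seed),
            class = "clutter_spec")
}

#' Per-target chest displacement on a time grid
#'
#' Integrates each target's rate schedule into a phase, so constant rates
#' give exact sinusoids and ramped schedules give chirps.
#'
#' @param targets List of [target_spec()] objects (at least one).
#' @param t Uniformly spaced time grid starting at 0, seconds.
#' @return Tibble with columns `time`, `target`, `displacement_m`.
#' @examples
#' tg <- list(target_spec(1.5, rate = 0.25, amplitude_m = 1))
#' chest_displacement(tg, seq(0, 2, by = 0.01))
#' @export
chest_displacement <- function(targets, t) {
  if (length(targets) == 0) abort("no targets")
  if (inherits(targets, "target_spec")) targets <- list(targets)
  purrr::imap_dfr(targets, function(tg, i) {
    f <- tg$rate_schedule(t)
    phi <- 2 * pi * cumtrapz(t, f)
    a <- tg$amplitude_m *
      (if (is.null(tg$amplitude_schedule)) 1 else tg$amplitude_schedule(t))
    tibble(
      time = t,
      target = tg$label %||% paste0("target_", i),
      displacement_m = a * sin(phi)
    )
  })
}

#' Round-trip delay of a target echo
#'
#' `tau(t) = 2 (d0 + x(t)) / c`: the two-way travel time of the pulse to a
#' chest at instantaneous distance `d0 + x(t)`.
#'
#' @param target A [target_spec()].
#' @param displacement_m Chest displacement series x(t), metres.
#' @param c_mps Propagation speed, m/s.
#' @return Delay series in seconds, same length as `displacement_m`.
#' @export
round_trip_delay <- function(target, displacement_m, c_mps = 2.998e8) {
  stopifnot(c_mps > 0)
  d <- target$distance_m + displacement_m
  if (any(d < 0)) abort("total target distance became negative")
  2 * d / c_mps
}

#' First-derivative Gaussian (monocycle) pulse template
#'
#' `p(t) = -(t / scale) exp(-t^2 / (2 scale^2))`, peak-normalised to 1.
#' The pulse is odd (`p(-t) = -p(t)`, `p(0) = 0`); its amplitude spectrum
#' peaks at `1 / (2 pi scale)` and the default scale puts the -10 dB band
#' at about 0.85-9.55 GHz.
#'
#' @param t_rel Time offsets from the pulse centre, seconds.
#' @param scale Width parameter, seconds (> 0).
#' @return Pulse amplitude at each offset.
#' @export
gaussian_monocycle <- function(t_rel, scale = 3.674e-11) {
  if (scale <= 0) abort("`scale` must be positive")
  u <- t_rel / scale
  -u * exp(-u^2 / 2) / exp(-0.5)
}

#' Simulate a UWB radar echo matrix from breathing targets
#'
#' Builds the J-by-N slow-time/fast-time matrix: at each slow-time instant
#' every target contributes a delayed, scaled monocycle across the fast-time
#' (range) axis, the delay modulated by its chest displacement.  A static
#' clutter profile and white Gaussian noise (calibrated against the echo
#' power) are then added.
#'
#' @param config A [radar_config()].
#' @param targets List of [target_spec()] objects; may be empty (clutter
#'   and noise only).
#' @param clutter A [clutter_spec()].
#' @return A `radar_matrix`: a J-by-N numeric matrix (rows = range bins,
#'   columns = slow-time samples) with attributes `slow_rate`, `fast_rate`,
#'   `bin_spacing_m`, and a `truth` list recording each target's true range
#'   bin and rate schedule.
#' @examples
#' cfg <- radar_config(n_slow = 512)
#' tg <- list(target_spec(1.5, rate = 0.2))
#' R <- generate_echo_matrix(cfg, tg, clutter_spec(amplitude = 0.5, snr_db = 10, seed = 1))
#' dim(R)
#' @export
generate_echo_matrix <- function(config, targets,
                                 clutter = clutter_spec()) {
  stopifnot(inherits(config, "radar_config"), inherits(clutter, "clutter_spec"))
  if (inherits(targets, "target_spec")) targets <- list(targets)
  J <- config$n_bins
  N <- config$n_slow
  t_slow <- (seq_len(N) - 1) / config$slow_rate
  tau_grid <- (seq_len(J) - 1) / config$fast_rate
  pad <- 6 * config$pulse_scale       # effective one-sided pulse support

  echo <- matrix(0, J, N)
  truth_rows <- list()
  for (i in seq_along(targets)) {
    tg <- targets[[i]]
    name <- tg$label %||% paste0("target_", i)
    x <- chest_displacement(list(tg), t_slow)$displacement_m
    tau_v <- round_trip_delay(tg, x, config$c_mps)
    if (min(tau_v) - pad < 0 || max(tau_v) + pad > tau_grid[J]) {
      abort(paste0("delay of ", name,
                   " falls outside the observable fast-time window"))
    }
    echo <- echo + tg$reflect *
      gaussian_monocycle(outer(tau_grid, tau_v, `-`), config$pulse_scale)
    tau0 <- 2 * tg$distance_m / config$c_mps
    truth_rows[[i]] <- tibble(
      target = name,
      distance_m = tg$distance_m,
      bin = as.integer(round(tau0 * config$fast_rate)) + 1L,
      amplitude_m = tg$amplitude_m,
      reflect = tg$reflect
    )
  }

  out <- echo
  with_seed(clutter$seed, {
    if (clutter$amplitude > 0) {
      profile <- clutter$amplitude * stats::rnorm(J)
      out <- out + profile            # recycled down columns: static in slow time
    }
    if (is.finite(clutter$snr_db) && length(targets) > 0) {
      p_echo <- mean(echo^2)
      p_noise <- p_echo * 10^(-clutter$snr_db / 10)
      noise <- stats::rnorm(J * N)
      noise <- noise * sqrt(p_noise / mean(noise^2))
      out <- out + matrix(noise, J, N)
    }
  })

  structure(
    out,
    class = c("radar_matrix", "matrix", "array"),
    slow_rate = config$slow_rate,
    fast_rate = config$fast_rate,
    bin_spacing_m = config$bin_spacing_m,
    truth = list(
      targets = if (length(truth_rows)) dplyr::bind_rows(truth_rows) else NULL,
      rate_schedules = lapply(targets, `[[`, "rate_schedule"),
      clutter = clutter[c("amplitude", "snr_db", "seed")]
    )
  )
}

#' @export
print.radar_matrix <- function(x, ...) {
  cat(sprintf(
    "<radar_matrix> %d range bins x %d slow-time samples (%.4g s @ %.6g Hz)\n",
    nrow(x), ncol(x), ncol(x) / attr(x, "slow_rate"), attr(x, "slow_rate")))
  tr <- attr(x, "truth")
  if (!is.null(tr$targets)) {
    cat("targets:\n")
    print(tr$targets)
  }
  invisible(x)
}

#' Two-tone respiration test signal
#'
#' Sum of unit-amplitude sinusoids at the given rates, optionally corrupted
#' by white Gaussian noise whose power is calibrated (exactly, by scaling
#' the realised noise vector) against the clean sum.  The clean components
#' are kept as attributes for correlation scoring.
#'
#' @param rates Distinct breathing rates in Hz, each below `rate / 2`.
#' @param duration Record length, seconds.
#' @param rate Sampling rate, Hz.
#' @param snr_db Signal-to-noise ratio in dB, or `NULL` for a clean signal.
#' @param seed Integer seed for the noise.
#' @return Tibble with columns `time`, `value`; attributes `rate`, `rates`,
#'   `components` (matrix of the clean sinusoids, one column per rate) and
#'   `clean` (their sum).
#' @examples
#' x <- simulate_two_tone(c(0.2, 0.35), duration = 50)
#' @export
simulate_two_tone <- function(rates = c(0.2, 0.35), duration = 50,
                              rate = 152.6, snr_db = NULL, seed = NULL) {
  if (anyDuplicated(rates)) abort("rates must be distinct")
  if (any(rates >= rate / 2)) abort("rates must be below the Nyquist rate")
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  comps <- sapply(rates, function(f) sin(2 * pi * f * t))
  colnames(comps) <- paste0("f_", rates)
  clean <- rowSums(comps)
  value <- clean
  if (!is.null(snr_db)) {
    p_noise <- mean(clean^2) * 10^(-snr_db / 10)
    noise <- with_seed(seed, stats::rnorm(n))
    noise <- noise * sqrt(p_noise / mean(noise^2))
    value <- clean + noise
  }
  structure(
    tibble(time = t, value = value),
    rate = rate, rates = rates, components = comps, clean = clean,
    snr_db = snr_db
  )
}
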