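# shared fixture builders (everything is generated in code)

fs_slow <- 152.6

make_tone <- function(f, duration = 50, rate = fs_slow, phase = 0) {
  t <- (seq_len(round(duration * rate)) - 1) / rate
  sin(2 * pi * f * t + phase)
}

# small radar scene: one breathing target at 1.5 m, defaults otherwise
small_scene <- function(n_slow = 2048, rate_hz = 0.25, snr_db = Inf,
                        clutter_amp = 0, seed = NULL) {
  cfg <- radar_config(n_slow = n_slow)
  tg <- list(target_spec(1.5, rate = rate_hz))
  R <- generate_echo_matrix(cfg, tg,
                            clutter_spec(amplitude = clutter_amp,
                                         snr_db = snr_db, seed = seed))
  list(config = cfg, targets = tg, R = R,
       true_bin = attr(R, "truth")$targets$bin)
}

# count local maxima exceeding frac * max (peak-count oracle for spectra)
count_peaks <- function(amp, frac = 0.5) {
  thr <- frac * max(amp)
  n <- length(amp)
  sum(amp[2:(n - 1)] > amp[1:(n - 2)] & amp[2:(n - 1)] >= amp[3:n] &
        amp[2:(n - 1)] > thr)
}
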