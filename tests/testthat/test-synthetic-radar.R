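# synthetic radar simulator: chest displacement, delays, pulse, echo matrix

test_that("chest displacement evaluates the sinusoidal model exactly", {
  tg <- list(target_spec(1.5, rate = 0.25, amplitude_m = 1))
  t <- seq(0, 1, by = 0.25)
  x <- chest_displacement(tg, t)
  # a sin(2 pi f t) with a = 1, f = 0.25: at t = 1 s the phase is pi/2
  expect_equal(x$displacement_m[t == 1], 1.0, tolerance = 1e-12)

  # zero amplitude: identically zero for every target
  tg0 <- list(target_spec(1, rate = 0.3, amplitude_m = 0),
              target_spec(1.2, rate = 0.2, amplitude_m = 0))
  x0 <- chest_displacement(tg0, seq(0, 10, by = 0.1))
  expect_true(all(x0$displacement_m == 0))

  expect_error(chest_displacement(list(), 0:10), "no targets")
})

test_that("two constant-rate targets put spectral peaks at their rates", {
  t <- (0:7629) / fs_slow
  tg <- list(target_spec(1.5, rate = 0.2),
             target_spec(1.5, rate = 0.35, amplitude_m = 0.004))
  x <- chest_displacement(tg, t) |>
    tidyr::pivot_wider(names_from = target, values_from = displacement_m)
  for (i in seq_along(tg)) {
    sp <- baseline_fft_spectrum(x[[i + 1]], rate = fs_slow)
    peak <- sp$frequency_hz[which.max(sp$amplitude)]
    expect_lt(abs(peak - c(0.2, 0.35)[i]), fs_slow / 7630 + 1e-9)  # one DFT bin
  }
})

test_that("ramped rate schedules integrate to the analytic chirp phase", {
  # f(t) = 0.2 + k t  =>  x(t) = a sin(2 pi (0.2 t + k t^2 / 2));
  # trapezoidal integration is exact for a linear integrand
  k <- (0.3 - 0.2) / 30
  tg <- list(target_spec(1.5, amplitude_m = 1,
                         rate = data.frame(time_s = c(0, 30),
                                           rate_hz = c(0.2, 0.3))))
  t <- seq(0, 30, by = 1 / fs_slow)
  got <- chest_displacement(tg, t)$displacement_m
  expect_equal(got, sin(2 * pi * (0.2 * t + k / 2 * t^2)), tolerance = 1e-9)
})

test_that("target_spec rejects invalid physiology", {
  expect_error(target_spec(-1, rate = 0.2), "positive")
  expect_error(target_spec(1.5, rate = 1.5), "\\[0, 1\\]")
  expect_error(target_spec(1.5, rate = 0.2, amplitude_m = -0.01), ">= 0")
})

test_that("round-trip delay matches the closed form 2 d / C", {
  tgA <- target_spec(1.5, rate = 0.2)
  expect_equal(round_trip_delay(tgA, 0), 1.0007e-8, tolerance = 1e-4)
  tgB <- target_spec(2, rate = 0.2)
  expect_equal(round_trip_delay(tgB, 0), 1.334e-8, tolerance = 1e-4)

  # breathing modulates the delay with peak-to-peak 2 * (2 a) / C
  a <- 0.005
  x <- a * sin(2 * pi * 0.2 * seq(0, 10, by = 1 / fs_slow))
  tau <- round_trip_delay(tgA, x)
  expect_equal(max(tau) - min(tau), 2 * (2 * a) / 2.998e8, tolerance = 1e-3)

  expect_error(round_trip_delay(tgA, -2), "negative")
})

test_that("monocycle pulse is odd with the advertised -10 dB band", {
  expect_identical(gaussian_monocycle(0), 0)
  t <- seq(-2e-10, 2e-10, by = 1e-12)
  expect_equal(gaussian_monocycle(-t), -gaussian_monocycle(t))
  expect_equal(max(abs(gaussian_monocycle(t))), 1, tolerance = 1e-3)

  # -10 dB band edges located by FFT of the sampled pulse
  fs <- 39e9
  tt <- seq(-10e-9, 10e-9, by = 1 / fs)   # long window: 0.05 GHz resolution
  p <- gaussian_monocycle(tt)
  sp <- baseline_fft_spectrum(p, rate = fs)
  amp <- sp$amplitude / max(sp$amplitude)
  above <- which(amp >= 10^(-10 / 20))
  lo <- sp$frequency_hz[min(above)]
  hi <- sp$frequency_hz[max(above)]
  expect_equal(lo, 0.85e9, tolerance = 0.07)
  expect_equal(hi, 9.55e9, tolerance = 0.07)
})

test_that("echo matrix defaults and clutter-only degenerate case", {
  cfg <- radar_config()
  expect_equal(cfg$slow_rate, 152.6)
  expect_equal(cfg$n_bins, 512)
  expect_equal(cfg$bin_spacing_m, 2.998e8 / (2 * 39e9))

  # no targets, no noise: the static clutter profile repeated N times
  R <- generate_echo_matrix(radar_config(n_slow = 64), list(),
                            clutter_spec(amplitude = 1, seed = 4))
  expect_true(all(apply(unclass(R), 1, function(r) max(r) - min(r)) == 0))
  expect_true(all(suppressWarnings(bin_variances(R))$variance == 0))
})

test_that("a static target lands in the range bin given by its delay", {
  cfg <- radar_config(n_slow = 32)
  tg <- list(target_spec(1.5, rate = 0.2, amplitude_m = 0))
  R <- generate_echo_matrix(cfg, tg)
  expect_true(all(unclass(R)[, 1] == unclass(R)[, 2]))
  tau0 <- 2 * 1.5 / 2.998e8
  expected_bin <- round(tau0 * 39e9) + 1
  # the monocycle is odd, so |amplitude| peaks one pulse-scale off centre
  expect_lte(abs(which.max(abs(unclass(R)[, 1])) - expected_bin), 2)
  expect_equal(attr(R, "truth")$targets$bin, expected_bin)
})

test_that("echo generation is linear in targets and seed-reproducible", {
  cfg <- radar_config(n_slow = 256)
  tgA <- target_spec(1.5, rate = 0.2)
  tgB <- target_spec(1.3, rate = 0.35, amplitude_m = 0.004)
  RA <- generate_echo_matrix(cfg, list(tgA))
  RB <- generate_echo_matrix(cfg, list(tgB))
  RAB <- generate_echo_matrix(cfg, list(tgA, tgB))
  expect_equal(unclass(RAB), unclass(RA) + unclass(RB), tolerance = 1e-12,
               ignore_attr = TRUE)

  cl <- clutter_spec(amplitude = 1, snr_db = 5, seed = 11)
  expect_identical(unclass(generate_echo_matrix(cfg, list(tgA), cl)),
                   unclass(generate_echo_matrix(cfg, list(tgA), cl)))
})

test_that("single-target echo energy concentrates at the true delay", {
  sc <- small_scene(n_slow = 256)
  E <- rowSums(unclass(sc$R)^2)
  win <- (sc$true_bin - 11):(sc$true_bin + 11)
  expect_gte(sum(E[win]) / sum(E), 0.99)
})

test_that("targets outside the observable window are reported by name", {
  cfg <- radar_config(n_slow = 16)   # window spans ~1.97 m
  expect_error(
    generate_echo_matrix(cfg, list(target_spec(2, rate = 0.2, label = "far_one"))),
    "far_one")
})

test_that("echo noise realises the requested SNR", {
  sc_clean <- small_scene(n_slow = 2048)
  sc_noisy <- small_scene(n_slow = 2048, snr_db = 3, seed = 2)
  noise <- unclass(sc_noisy$R) - unclass(sc_clean$R)
  snr <- 10 * log10(mean(unclass(sc_clean$R)^2) / mean(noise^2))
  expect_equal(snr, 3, tolerance = 0.03)
})

test_that("two-tone generator: determinism, SNR calibration, ground truth", {
  x1 <- simulate_two_tone(c(0.2, 0.35), 10, snr_db = -10, seed = 5)
  x2 <- simulate_two_tone(c(0.2, 0.35), 10, snr_db = -10, seed = 5)
  expect_identical(x1$value, x2$value)

  expect_error(simulate_two_tone(c(0.2, 0.2), 10), "distinct")
  expect_error(simulate_two_tone(c(0.2, 80), 10), "Nyquist")

  # realised SNR recomputed from the generated arrays
  clean <- attr(x1, "clean")
  snr <- 10 * log10(mean(clean^2) / mean((x1$value - clean)^2))
  expect_equal(snr, -10, tolerance = 0.001)

  comps <- attr(x1, "components")
  expect_equal(ncol(comps), 2)
  expect_equal(rowSums(comps), clean)
})
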