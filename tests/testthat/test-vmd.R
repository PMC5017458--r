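# VMD core: mirror extension, ADMM updates, convergence, full decomposition

test_that("mirror extension reflects half the signal onto each end", {
  ext <- mirror_extend(c(1, 2, 3, 4))
  expect_equal(ext$values, c(2, 1, 1, 2, 3, 4, 4, 3))
  expect_equal(ext$start, 3)
  expect_equal(ext$end, 6)

  # round trip restores the original exactly, odd lengths included
  for (n in c(2, 5, 17, 100)) {
    x <- rnorm(n)
    ext <- mirror_extend(x)
    expect_length(ext$values, 2 * n)
    expect_identical(ext$values[ext$start:ext$end], x)
    # reflection leaves no amplitude jump at either seam
    expect_equal(ext$values[ext$start - 1], x[1])
    expect_equal(ext$values[ext$end + 1], x[n])
  }
  expect_error(mirror_extend(1), "at least 2")
})

test_that("mode update is the closed-form Wiener filter, bin by bin", {
  set.seed(7)
  nb <- 64
  grid <- (0:(nb - 1)) / (2 * nb)
  f_hat <- complex(real = rnorm(nb), imaginary = rnorm(nb))
  others <- complex(real = rnorm(nb), imaginary = rnorm(nb))
  lam <- complex(real = rnorm(nb), imaginary = rnorm(nb))
  omega_k <- 0.11
  alpha <- 20000
  got <- vmd_update_mode(f_hat, others, lam, grid, omega_k, alpha)
  # independent per-bin scalar evaluation
  expected <- sapply(seq_len(nb), function(j) {
    (f_hat[j] - others[j] + lam[j] / 2) / (1 + 2 * alpha * (grid[j] - omega_k)^2)
  })
  expect_lt(max(Mod(got - expected)) / max(Mod(expected)), 1e-12)

  # gain is exactly 1 at the mode's own centre frequency (K = 1, lambda = 0)
  zero <- complex(real = rep(0, nb))
  at_centre <- vmd_update_mode(f_hat, zero, zero, grid, grid[12], alpha)
  expect_equal(at_centre[12], f_hat[12])

  expect_error(vmd_update_mode(f_hat, others[-1], lam, grid, 0.1, alpha),
               "grid")
})

test_that("centre-frequency update is the power centroid", {
  grid <- seq(0, 0.5, by = 0.001)
  pt <- complex(real = rep(0, length(grid)))
  pt[grid == 0.3] <- 5 + 2i
  expect_equal(vmd_update_center_frequency(pt, grid), 0.3)

  sym <- complex(real = rep(0, length(grid)))
  sym[grid == 0.2] <- 3i
  sym[grid == 0.4] <- 3
  expect_equal(vmd_update_center_frequency(sym, grid), 0.3)

  set.seed(1)
  rnd <- complex(real = rnorm(length(grid)), imaginary = rnorm(length(grid)))
  brute <- sum(grid * Mod(rnd)^2) / sum(Mod(rnd)^2)
  expect_equal(vmd_update_center_frequency(rnd, grid), brute)

  zero <- complex(real = rep(0, length(grid)))
  expect_warning(kept <- vmd_update_center_frequency(zero, grid, previous = 0.17),
                 "previous")
  expect_equal(kept, 0.17)
})

test_that("dual ascent accumulates tau times the reconstruction residual", {
  set.seed(2)
  nb <- 32
  lam <- complex(real = rnorm(nb), imaginary = rnorm(nb))
  f_hat <- complex(real = rnorm(nb), imaginary = rnorm(nb))
  sum_modes <- complex(real = rnorm(nb), imaginary = rnorm(nb))

  expect_identical(vmd_update_dual(lam, f_hat, sum_modes, 0), lam)
  expect_equal(vmd_update_dual(lam, f_hat, f_hat, 1), lam)
  got <- vmd_update_dual(lam, f_hat, sum_modes, 0.5)
  expect_equal(got - lam, 0.5 * (f_hat - sum_modes))
})

test_that("convergence residual is the summed relative mode change", {
  set.seed(3)
  u_old <- matrix(complex(real = rnorm(40), imaginary = rnorm(40)), 20, 2)
  u_new <- u_old + matrix(complex(real = 0.001 * rnorm(40)), 20, 2)

  same <- vmd_convergence(u_old, u_old, 1e-6)
  expect_true(same$converged)
  expect_equal(same$residual, 0)

  brute <- sum(sapply(1:2, function(k) {
    sum(Mod(u_new[, k] - u_old[, k])^2) / sum(Mod(u_old[, k])^2)
  }))
  expect_equal(vmd_convergence(u_new, u_old, 1e-6)$residual, brute)

  # zero-energy previous iterate must not fake convergence through 0/0
  z <- matrix(complex(real = rep(0, 20)), 20, 1)
  nz <- matrix(complex(real = rnorm(20)), 20, 1)
  expect_false(vmd_convergence(nz, z, 1e-6)$converged)
  expect_true(vmd_convergence(z, z, 1e-6)$converged)
})

test_that("zero input collapses to zero modes at the first iteration", {
  fit <- vmd(rep(0, 256), rate = fs_slow, k = 2)
  expect_true(fit$converged)
  expect_equal(fit$n_iterations, 1)
  expect_true(all(fit$modes == 0))
})

test_that("K = 1 centre frequency agrees with the FFT peak", {
  x <- make_tone(0.3, duration = 50)
  fit <- vmd(x, rate = fs_slow, k = 1)
  sp <- amp <- baseline_fft_spectrum(x, rate = fs_slow)
  fft_peak <- sp$frequency_hz[which.max(sp$amplitude)]
  bin <- fs_slow / (2 * length(x))    # DFT bin of the extended record
  expect_lt(abs(fit$center_frequencies[1] - fft_peak), bin + 1e-9)
})

test_that("clean two-tone record splits into its components", {
  x <- simulate_two_tone(c(0.2, 0.35), duration = 50)
  fit <- vmd(x, k = 2)
  expect_true(fit$converged)
  bin <- fs_slow / (2 * nrow(x))
  expect_lt(abs(fit$center_frequencies[1] - 0.2), bin)
  expect_lt(abs(fit$center_frequencies[2] - 0.35), bin)

  # separation quality away from the trim boundary (the mirror-extension
  # seam tapers mode amplitude over the outermost samples)
  comps <- attr(x, "components")
  n <- nrow(x)
  interior <- round(0.1 * n):round(0.9 * n)
  expect_gte(cor(fit$modes[interior, 1], comps[interior, 1]), 0.99)
  expect_gte(cor(fit$modes[interior, 2], comps[interior, 2]), 0.99)
})

test_that("tones separated by 0.1 Hz or more stay separable", {
  for (f2 in c(0.3, 0.45)) {
    x <- simulate_two_tone(c(0.2, f2), duration = 50)
    fit <- vmd(x, k = 2)
    comps <- attr(x, "components")
    n <- nrow(x)
    interior <- round(0.1 * n):round(0.9 * n)
    expect_gte(cor(fit$modes[interior, 1], comps[interior, 1]), 0.99)
    expect_gte(cor(fit$modes[interior, 2], comps[interior, 2]), 0.99)
  }
})

test_that("decomposition is deterministic and init-order invariant", {
  x <- simulate_two_tone(c(0.2, 0.35), duration = 30)
  f1 <- vmd(x, k = 2)
  f2 <- vmd(x, k = 2)
  expect_identical(f1$modes, f2$modes)
  expect_identical(f1$center_frequencies, f2$center_frequencies)

  # explicit start frequencies, given in either order, sort to one answer
  fa <- vmd(x, k = 2, init = c(0, 38.15))
  fb <- vmd(x, k = 2, init = c(38.15, 0))
  # the alternating updates run in a different order, so agreement is to
  # the convergence tolerance, not bit-exact
  expect_equal(fa$center_frequencies, fb$center_frequencies, tolerance = 1e-3)
})

test_that("centre frequencies always stay within [0, rate/2]", {
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(300)
    fit <- suppressWarnings(vmd(x, rate = fs_slow, k = 3, max_iterations = 40))
    expect_true(all(fit$center_frequencies >= 0))
    expect_true(all(fit$center_frequencies <= fs_slow / 2))
    expect_true(all(is.finite(fit$modes)))
    expect_true(all(diff(fit$center_frequencies) >= 0))
  }
})

test_that("dual ascent enforces near-exact reconstruction of clean input", {
  x <- simulate_two_tone(c(0.2, 0.35), duration = 30)
  filt <- lowpass_zero_phase(x$value, fs_slow, 0.7)
  fit <- vmd(filt, rate = fs_slow, k = 2, tau = 1)
  rel <- sqrt(sum((filt - rowSums(fit$modes))^2) / sum(filt^2))
  expect_lte(rel, 0.05)
})

test_that("non-convergence warns and is reported, never an error", {
  x <- simulate_two_tone(c(0.2, 0.35), duration = 20)
  expect_warning(fit <- vmd(x, k = 2, max_iterations = 2), "did not converge")
  expect_false(fit$converged)
  expect_equal(fit$n_iterations, 2)
})

test_that("parameter validation rejects degenerate requests", {
  x <- make_tone(0.2, duration = 5)
  expect_error(vmd(1:8, rate = 10, k = 1), "too short")
  expect_error(vmd(x, rate = fs_slow, k = 0), ">= 1")
  expect_error(vmd(x, rate = fs_slow, k = 2, alpha = -1), "alpha")
  df <- tibble::tibble(time = c(0, 1, 3, 6), value = rnorm(4))
  expect_error(vmd(df, k = 1), "non-uniform")
})

test_that("respiration-mode recognition applies band and energy rules", {
  mk_fit <- function(freqs, scales) {
    t <- (0:999) / fs_slow
    modes <- sapply(seq_along(freqs),
                    function(i) scales[i] * sin(2 * pi * freqs[i] * t))
    colnames(modes) <- paste0("mode_", seq_along(freqs))
    structure(list(modes = modes, center_frequencies = freqs, rate = fs_slow,
                   k = length(freqs)), class = "vmd")
  }
  # equal energies at 0.05 / 0.2 / 0.35 Hz: only the in-band pair survives
  expect_equal(select_respiration_modes(mk_fit(c(0.05, 0.2, 0.35), c(1, 1, 1))),
               c(2, 3))
  # an in-band mode with ~0.1% energy fraction is rejected
  expect_equal(select_respiration_modes(mk_fit(c(0.2, 0.35), c(0.03, 1))), 2)
  # nothing in band: empty selection with a warning
  expect_warning(sel <- select_respiration_modes(mk_fit(c(0.05, 2), c(1, 1))),
                 "no respiration modes")
  expect_length(sel, 0)
})

test_that("tidy and glance summarise a fit in broom style", {
  x <- simulate_two_tone(c(0.2, 0.35), duration = 20)
  fit <- vmd(x, k = 2)
  td <- tidy(fit)
  expect_equal(td$mode, 1:2)
  expect_equal(td$rate_bpm, 60 * td$center_frequency_hz)
  expect_equal(sum(td$energy_fraction), 1)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$k, 2)
})
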