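#' Mirror-symmetric extension of a signal
#'
#' Reflects the first half of the signal onto the front and the second half
#' onto the back, doubling its length.  The decomposition operates on the
#' extension (whose ends meet without discontinuity), and the `start`/`end`
#' indices restore the original support exactly afterwards.
#'
#' @param x Numeric signal of length >= 2.
#' @return List with `values` (length `2 * length(x)`), and the 1-based
#'   `start` and `end` indices of the original samples inside `values`.
#' @examples
#' mirror_extend(c(1, 2, 3, 4))$values  # 2 1 1 2 3 4 4 3
#' @export
mirror_extend <- function(x) {
  n <- length(x)
  if (n < 2) abort("signal must have at least 2 samples")
  n_front <- n %/% 2L
  n_back <- n - n_front
  list(
    values = c(rev(x[seq_len(n_front)]), x, rev(x[(n - n_back + 1L):n])),
    start = n_front + 1L,
    end = n_front + n
  )
}

#' One ADMM mode update (Wiener filter of the residual)
#'
#' Updates a mode's one-sided spectrum as
#' `(f_hat - sum_other_hat + lambda_hat / 2) / (1 + 2 alpha (grid - omega_k)^2)`:
#' the current residual passed through a Wiener filter centred on the
#' mode's frequency, with bandwidth set by `alpha` (larger `alpha`, narrower
#' mode).  `freq_grid` and `omega_k` must share units; [vmd()] uses
#' cycles/sample internally, which is the convention under which the
#' customary `alpha = 20000` applies.
#'
#' @param f_hat One-sided spectrum of the (extended) input signal.
#' @param sum_other_hat Sum of the other modes' spectra on the same grid.
#' @param lambda_hat Dual-variable spectrum on the same grid.
#' @param freq_grid Non-negative frequency grid.
#' @param omega_k Centre frequency of the mode being updated.
#' @param alpha Bandwidth-penalty weight (> 0).
#' @return Updated complex mode spectrum.
#' @export
vmd_update_mode <- function(f_hat, sum_other_hat, lambda_hat, freq_grid,
                            omega_k, alpha) {
  nlen <- length(f_hat)
  if (length(sum_other_hat) != nlen || length(lambda_hat) != nlen ||
      length(freq_grid) != nlen) {
    abort("spectra and frequency grid must share one grid")
  }
  (f_hat - sum_other_hat + lambda_hat / 2) /
    (1 + 2 * alpha * (freq_grid - omega_k)^2)
}

#' Centre-frequency update (power-spectrum centroid)
#'
#' `omega_k = sum(grid * |u_hat|^2) / sum(|u_hat|^2)` over non-negative
#' frequencies: the centre of mass of the mode's power spectrum.  An
#' all-zero spectrum has no centroid; the previous value is kept (with a
#' warning unless `quiet`) to avoid a 0/0.
#'
#' @param mode_hat One-sided complex mode spectrum.
#' @param freq_grid Matching non-negative frequency grid.
#' @param previous Centre frequency to fall back on for a zero spectrum.
#' @param quiet Suppress the zero-spectrum warning (used by the inner loop).
#' @return Centre frequency in the units of `freq_grid`.
#' @export
vmd_update_center_frequency <- function(mode_hat, freq_grid, previous = NULL,
                                        quiet = FALSE) {
  if (length(mode_hat) != length(freq_grid)) {
    abort("spectrum and frequency grid must share one grid")
  }
  p <- Mod(mode_hat)^2
  s <- sum(p)
  if (s == 0) {
    if (!quiet) warn("all-zero mode spectrum: keeping previous centre frequency")
    return(previous %||% NA_real_)
  }
  sum(freq_grid * p) / s
}

#' Dual-ascent update of the Lagrangian multiplier
#'
#' `lambda_hat <- lambda_hat + tau * (f_hat - sum_modes_hat)`.  With
#' `tau = 0` (the denoising setting) the dual stays identically zero and
#' exact reconstruction is not enforced.
#'
#' @param lambda_hat Current dual spectrum.
#' @param f_hat Input-signal spectrum on the same grid.
#' @param sum_modes_hat Sum of all mode spectra on the same grid.
#' @param tau_dual Ascent step (>= 0).
#' @return Updated dual spectrum.
#' @export
vmd_update_dual <- function(lambda_hat, f_hat, sum_modes_hat, tau_dual) {
  if (length(f_hat) != length(lambda_hat) ||
      length(sum_modes_hat) != length(lambda_hat)) {
    abort("spectra must share one grid")
  }
  lambda_hat + tau_dual * (f_hat - sum_modes_hat)
}

#' Convergence check on successive mode iterates
#'
#' Residual `sum_k ||u_k_new - u_k_old||^2 / ||u_k_old||^2`, compared
#' against `epsilon`.  A mode with zero old energy contributes 0 when its
#' update is also zero, and `Inf` otherwise, so a run cannot report
#' convergence through a 0/0.
#'
#' @param u_new,u_old Complex matrices (frequency bins by modes) of the new
#'   and previous iterates.
#' @param epsilon Convergence tolerance (> 0).
#' @return List with `converged` (logical) and `residual`.
#' @export
vmd_convergence <- function(u_new, u_old, epsilon = 1e-6) {
  u_new <- as.matrix(u_new)
  u_old <- as.matrix(u_old)
  if (!all(dim(u_new) == dim(u_old))) abort("iterates must share dimensions")
  contrib <- vapply(seq_len(ncol(u_new)), function(k) {
    num <- sum(Mod(u_new[, k] - u_old[, k])^2)
    den <- sum(Mod(u_old[, k])^2)
    if (den == 0) {
      if (num == 0) 0 else Inf
    } else {
      num / den
    }
  }, numeric(1))
  residual <- sum(contrib)
  list(converged = residual < epsilon, residual = residual)
}

vmd_init_omega <- function(init, k, rate, seed, f_hat = NULL, freqs = NULL) {
  if (is.numeric(init)) {
    if (length(init) != k) abort("numeric `init` must supply one frequency per mode")
    if (any(init < 0 | init > rate / 2)) abort("`init` frequencies must lie in [0, rate/2]")
    return(init / rate)                       # Hz -> cycles/sample
  }
  switch(match.arg(init, c("peaks", "uniform", "zero", "random")),
    peaks = vmd_init_peaks(f_hat, freqs, k),
    uniform = 0.5 * (seq_len(k) - 1) / k,
    zero = numeric(k),
    random = with_seed(seed, sort(stats::runif(k, 0, 0.25)))
  )
}

# start the modes on the k tallest local maxima of the input amplitude
# spectrum (deterministic, data-adaptive); missing peaks are filled with
# evenly spaced positions
vmd_init_peaks <- function(f_hat, freqs, k) {
  amp <- Mod(f_hat)
  n <- length(amp)
  is_peak <- c(FALSE, amp[2:(n - 1)] > amp[1:(n - 2)] &
                 amp[2:(n - 1)] >= amp[3:n], FALSE)
  idx <- which(is_peak)
  idx <- idx[order(amp[idx], decreasing = TRUE)]
  omega <- freqs[utils::head(idx, k)]
  if (length(omega) < k) {
    omega <- c(omega, 0.5 * (seq_len(k - length(omega)) - 1) / k)
  }
  sort(omega)
}

#' Variational mode decomposition
#'
#' Splits a real 1-D signal into `k` narrowband modes with centre
#' frequencies by the alternating-direction scheme: the signal is
#' mirror-extended, transformed, and on the non-negative half of the
#' spectrum each mode is repeatedly re-estimated as a Wiener-filtered
#' residual ([vmd_update_mode()]) while its centre frequency tracks the
#' power centroid ([vmd_update_center_frequency()]) and an optional dual
#' ascent ([vmd_update_dual()]) pushes the mode sum toward exact
#' reconstruction.  Iterations stop when the relative change of all modes
#' falls below `epsilon` ([vmd_convergence()]) or at `max_iterations`.
#' Modes are inverse-transformed under conjugate symmetry (real output),
#' trimmed to the original support, and sorted by ascending centre
#' frequency.
#'
#' @param x Numeric signal, or a data frame with `time` and `value`.
#' @param rate Sampling rate in Hz (inferred from `time` if omitted).
#' @param k Number of modes.
#' @param alpha Bandwidth-penalty weight; the default 20000 (with the
#'   internal cycles/sample grid) suits respiration separation at around
#'   150 Hz slow-time sampling.
#' @param tau Dual ascent step; 0 (default) for noisy/denoising use,
#'   positive to enforce reconstruction of clean signals.
#' @param epsilon Convergence tolerance on the relative mode change.
#' @param max_iterations Iteration cap; non-convergence yields a warning
#'   and `converged = FALSE`, never an error.
#' @param init Centre-frequency initialisation: `"peaks"` (default; the
#'   `k` tallest local maxima of the input amplitude spectrum — the
#'   standard data-adaptive start, deterministic and robust against a mode
#'   latching onto broadband noise), `"uniform"` (evenly spaced over the
#'   one-sided band, starting at 0), `"zero"`, `"random"` (seeded), or a
#'   numeric vector of `k` start frequencies in Hz.
#' @param seed Seed used only by `init = "random"`.
#' @return A `vmd` object: list with `modes` (matrix, one column per mode,
#'   same number of rows as input), `center_frequencies` (Hz, ascending),
#'   `n_iterations`, `converged`, `final_residual`, `rate`, and the
#'   parameters used.
#' @examples
#' x <- simulate_two_tone(c(0.2, 0.35), duration = 50)
#' fit <- vmd(x, k = 2)
#' fit$center_frequencies
#' @export
vmd <- function(x, rate = NULL, k = 2, alpha = 20000, tau = 0,
                epsilon = 1e-6, max_iterations = 500, init = "peaks",
                seed = NULL) {
  sig <- as_slow_time(x, rate)
  v <- sig$values
  fs <- sig$rate
  n <- length(v)
  if (n < 16) abort("signal too short to decompose (need >= 16 samples)")
  if (k < 1) abort("`k` must be >= 1")
  if (k >= n / 4) abort("`k` must be smaller than length(x) / 4")
  if (alpha <= 0) abort("`alpha` must be positive")
  if (tau < 0) abort("`tau` must be >= 0")
  if (epsilon <= 0) abort("`epsilon` must be positive")

  ext <- mirror_extend(v)
  f <- ext$values
  Tn <- length(f)                        # even: 2 n
  half <- seq_len(Tn %/% 2L + 1L)
  freqs <- (half - 1) / Tn               # cycles/sample, 0..1/2

  f_hat <- stats::fft(f)[half]
  nb <- length(half)
  u_hat <- matrix(complex(real = 0), nb, k)
  lambda_hat <- complex(real = rep(0, nb))
  omega <- vmd_init_omega(init, k, fs, seed, f_hat = f_hat, freqs = freqs)

  sum_u <- complex(real = rep(0, nb))
  it <- 0L
  converged <- FALSE
  residual <- Inf
  while (it < max_iterations && !converged) {
    it <- it + 1L
    u_prev <- u_hat
    for (kk in seq_len(k)) {
      sum_u <- sum_u - u_hat[, kk]
      u_new <- vmd_update_mode(f_hat, sum_u, lambda_hat, freqs, omega[kk], alpha)
      omega[kk] <- vmd_update_center_frequency(u_new, freqs,
                                               previous = omega[kk],
                                               quiet = TRUE)
      sum_u <- sum_u + u_new
      u_hat[, kk] <- u_new
    }
    if (tau > 0) {
      lambda_hat <- vmd_update_dual(lambda_hat, f_hat, sum_u, tau)
    }
    conv <- vmd_convergence(u_hat, u_prev, epsilon)
    residual <- conv$residual
    converged <- conv$converged
  }
  if (!converged) {
    warn(sprintf("VMD did not converge in %d iterations (residual %.3g)",
                 max_iterations, residual))
  }

  ord <- order(omega)
  omega <- omega[ord]
  u_hat <- u_hat[, ord, drop = FALSE]
  if (k > 1 && any(diff(omega) * fs < 1e-4)) {
    warn("two modes share a centre frequency; downstream selection will dedupe")
  }

  modes <- vapply(seq_len(k), function(kk) {
    spec <- complex(real = rep(0, Tn))
    spec[half] <- u_hat[, kk]
    if (Tn > 2) spec[Tn:(Tn %/% 2L + 2L)] <- Conj(u_hat[2:(Tn %/% 2L), kk])
    Re(stats::fft(spec, inverse = TRUE) / Tn)[ext$start:ext$end]
  }, numeric(n))
  colnames(modes) <- paste0("mode_", seq_len(k))

  structure(
    list(
      modes = modes,
      center_frequencies = omega * fs,
      rate = fs,
      n_iterations = it,
      converged = converged,
      final_residual = residual,
      k = k, alpha = alpha, tau = tau, epsilon = epsilon,
      init = init
    ),
    class = "vmd"
  )
}

#' Identify the respiration modes of a decomposition
#'
#' Keeps modes whose centre frequency falls inside the respiration band and
#' whose share of the total mode energy passes a threshold; near-duplicate
#' modes (time-domain correlation > 0.98) are reduced to the more energetic
#' one.  Returned indices refer to columns of `object$modes` and are
#' ordered by ascending centre frequency.
#'
#' @param object A [vmd()] result.
#' @param band Respiration band `c(low, high)` in Hz.
#' @param energy_fraction Minimum fraction of total mode energy.
#' @return Integer vector of mode indices (possibly empty, with a warning).
#' @export
select_respiration_modes <- function(object, band = c(0.1, 0.7),
                                     energy_fraction = 0.05) {
  stopifnot(inherits(object, "vmd"), length(band) == 2, band[1] < band[2])
  energy <- colSums(object$modes^2)
  frac <- energy / sum(energy)
  omega <- object$center_frequencies
  sel <- which(omega >= band[1] & omega <= band[2] & frac >= energy_fraction)
  if (length(sel) > 1) {
    keep <- rep(TRUE, length(sel))
    for (a in seq_along(sel)) {
      for (b in seq_len(a - 1)) {
        if (keep[a] && keep[b] &&
            abs(stats::cor(object$modes[, sel[a]], object$modes[, sel[b]])) > 0.98) {
          drop <- if (energy[sel[a]] >= energy[sel[b]]) b else a
          keep[drop] <- FALSE
          warn("dropping a near-duplicate mode (correlation > 0.98)")
        }
      }
    }
    sel <- sel[keep]
  }
  if (length(sel) == 0) warn("no respiration modes found")
  unname(sel[order(omega[sel])])
}
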