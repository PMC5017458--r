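# shared internal helpers

# evaluate `code` under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# analytic signal z(t) = x(t) + i H{x}(t) via the FFT one-sided-spectrum
# construction; |z| is the amplitude envelope, Arg(z) the instantaneous phase
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) abort("signal too short for analytic-signal construction")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# analytic signal with linear-prediction edge handling: both ends are
# continued by an AR(2) Burg fit (which continues a narrowband oscillation
# phase-coherently), the outer half of each continuation is cosine-tapered
# to zero so the circular FFT sees no seam, and the original support is
# trimmed back out.  Falls back to mirror extension for very short or
# degenerate inputs.
analytic_extend <- function(x) {
  n <- length(x)
  n_ext <- n %/% 2L
  fit <- tryCatch(
    stats::ar.burg(x, aic = FALSE, order.max = 2, demean = FALSE),
    error = function(e) NULL
  )
  if (is.null(fit) || length(fit$ar) < 1 || n_ext < 8) {
    ext <- mirror_extend(x)
    return(analytic_signal(ext$values)[ext$start:ext$end])
  }
  a <- fit$ar
  fwd <- as.numeric(stats::filter(rep(0, n_ext), a, method = "recursive",
                                  init = rev(utils::tail(x, length(a)))))
  bwd <- rev(as.numeric(stats::filter(rep(0, n_ext), a, method = "recursive",
                                      init = utils::head(x, length(a)))))
  h <- n_ext %/% 2L
  taper <- 0.5 * (1 + cos(pi * seq_len(h) / h))
  fwd[(n_ext - h + 1L):n_ext] <- fwd[(n_ext - h + 1L):n_ext] * taper
  bwd[seq_len(h)] <- bwd[seq_len(h)] * rev(taper)
  analytic_signal(c(bwd, x, fwd))[(n_ext + 1L):(n_ext + n)]
}

# centered moving average, truncated and renormalised at the edges.
# NA samples are dropped from their windows (all-NA window -> NA).
moving_average <- function(x, width) {
  n <- length(x)
  width <- max(1L, as.integer(round(width)))
  h <- width %/% 2L
  v <- ifelse(is.na(x), 0, x)
  w <- as.numeric(!is.na(x))
  cv <- c(0, cumsum(v))
  cw <- c(0, cumsum(w))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  sv <- cv[hi + 1L] - cv[lo]
  sw <- cw[hi + 1L] - cw[lo]
  out <- sv / sw
  out[sw == 0] <- NA_real_
  out
}

# cumulative trapezoidal integral of y over uniformly spaced t
cumtrapz <- function(t, y) {
  n <- length(y)
  if (n < 2) return(numeric(n))
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

# coerce a numeric vector or a (time, value) data frame into an internal
# uniformly-sampled signal representation: list(values, rate)
as_slow_time <- function(x, rate = NULL) {
  if (is.data.frame(x)) {
    if (!all(c("time", "value") %in% names(x))) {
      abort("signal data frame must have columns `time` and `value`")
    }
    dt <- diff(x$time)
    if (length(dt) < 1) abort("signal must have at least 2 samples")
    if ((max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
      abort("non-uniform sampling: `time` must be an evenly spaced grid")
    }
    rate <- rate %||% attr(x, "rate") %||% (1 / stats::median(dt))
    list(values = as.numeric(x$value), rate = rate)
  } else {
    rate <- rate %||% attr(x, "rate")
    if (is.null(rate)) abort("`rate` must be supplied for a bare numeric signal")
    list(values = as.numeric(x), rate = rate)
  }
}

# one-sided amplitude spectrum of a real signal
amplitude_spectrum <- function(x, rate) {
  n <- length(x)
  X <- stats::fft(x)
  half <- seq_len(n %/% 2 + 1L)
  amp <- Mod(X[half]) / n
  # interior bins carry the energy of both spectral halves
  dbl <- half > 1 & (half < n / 2 + 1 | n %% 2 == 1)
  amp[dbl] <- 2 * amp[dbl]
  tibble(frequency_hz = (half - 1) * rate / n, amplitude = amp)
}
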