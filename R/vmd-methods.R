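#' @export
print.vmd <- function(x, ...) {
  cat(sprintf("<vmd> k = %d modes, alpha = %g, tau = %g\n", x$k, x$alpha, x$tau))
  cat(sprintf("  %d samples @ %.6g Hz; %s after %d iterations (residual %.3g)\n",
              nrow(x$modes), x$rate,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$final_residual))
  cat("  centre frequencies (Hz):",
      paste(sprintf("%.4g", x$center_frequencies), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a VMD fit: one row per mode
#'
#' @param x A [vmd()] result.
#' @param ... Unused.
#' @return Tibble with `mode`, `center_frequency_hz`, `rate_bpm`
#'   (`60 * center_frequency_hz`), `energy`, `energy_fraction`.
#' @export
tidy.vmd <- function(x, ...) {
  energy <- colSums(x$modes^2)
  tibble(
    mode = seq_len(x$k),
    center_frequency_hz = x$center_frequencies,
    rate_bpm = 60 * x$center_frequencies,
    energy = energy,
    energy_fraction = energy / sum(energy)
  )
}

#' One-row summary of a VMD fit
#'
#' @param x A [vmd()] result.
#' @param ... Unused.
#' @export
glance.vmd <- function(x, ...) {
  tibble(
    k = x$k, alpha = x$alpha, tau = x$tau, epsilon = x$epsilon,
    n_iterations = x$n_iterations, converged = x$converged,
    final_residual = x$final_residual
  )
}

#' Mode waveforms of a VMD fit in long form
#'
#' @param object A [vmd()] result.
#' @return Tibble with `time`, `mode`, `value`.
#' @export
vmd_modes <- function(object) {
  stopifnot(inherits(object, "vmd"))
  as_tibble(object$modes) |>
    dplyr::mutate(time = (dplyr::row_number() - 1) / object$rate) |>
    tidyr::pivot_longer(dplyr::starts_with("mode_"),
                        names_to = "mode", values_to = "value",
                        names_prefix = "mode_",
                        names_transform = as.integer)
}

#' Plot the modes of a VMD fit
#'
#' @param object A [vmd()] result.
#' @param ... Unused.
#' @return A ggplot: one facet per mode, labelled with its centre frequency.
#' @export
autoplot.vmd <- function(object, ...) {
  df <- vmd_modes(object)
  labs <- sprintf("mode %d (%.3g Hz)", seq_len(object$k),
                  object$center_frequencies)
  df$mode <- factor(df$mode, levels = seq_len(object$k), labels = labs)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~mode, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude")
}

#' Plot a radar matrix as a range-time image
#'
#' @param object A `radar_matrix`.
#' @param max_cols Slow-time columns are thinned to at most this many.
#' @param ... Unused.
#' @export
autoplot.radar_matrix <- function(object, max_cols = 1000, ...) {
  step <- max(1L, floor(ncol(object) / max_cols))
  cols <- seq(1L, ncol(object), by = step)
  df <- expand.grid(bin = seq_len(nrow(object)), col = cols)
  df$value <- unclass(object)[cbind(df$bin, df$col)]
  df$time <- (df$col - 1) / attr(object, "slow_rate")
  df$range_m <- (df$bin - 1) * attr(object, "bin_spacing_m")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$range_m,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "slow time (s)", y = "range (m)", fill = "echo")
}
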