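# CSV + JSON-sidecar persistence for radar matrices and derived tables

#' Write a radar matrix to CSV with a JSON metadata sidecar
#'
#' One CSV row per range bin (fast time down, slow time across), no header;
#' sampling metadata and the ground-truth target table (when present) go to
#' `<path>.json`.
#'
#' @param R A `radar_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_radar_csv <- function(R, path) {
  utils::write.table(unclass(R), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  tr <- attr(R, "truth")
  meta <- list(
    slow_rate = attr(R, "slow_rate"),
    fast_rate = attr(R, "fast_rate"),
    bin_spacing_m = attr(R, "bin_spacing_m"),
    n_bins = nrow(R),
    n_slow = ncol(R),
    clutter = tr$clutter,
    targets = tr$targets
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a radar matrix written by [write_radar_csv()]
#'
#' @param path CSV path; `<path>.json` must sit beside it.
#' @return A `radar_matrix`.
#' @export
read_radar_csv <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    abort(paste0("metadata sidecar not found: ", meta_path))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  values <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(values) <- NULL
  structure(
    values,
    class = c("radar_matrix", "matrix", "array"),
    slow_rate = meta$slow_rate,
    fast_rate = meta$fast_rate,
    bin_spacing_m = meta$bin_spacing_m,
    truth = list(
      targets = if (!is.null(meta$targets)) as_tibble(meta$targets) else NULL,
      clutter = meta$clutter
    )
  )
}

#' Write a slow-time signal to CSV
#'
#' Columns `time`, `value`; sampling metadata goes to `<path>.json`.
#'
#' @param signal Tibble from [extract_slow_time()] or [simulate_two_tone()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path) {
  readr::write_csv(as_tibble(signal[c("time", "value")]), path)
  jsonlite::write_json(
    list(rate = attr(signal, "rate"),
         origin_bin = attr(signal, "origin_bin"),
         rates = attr(signal, "rates"),
         snr_db = attr(signal, "snr_db")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a slow-time signal written by [write_signal_csv()]
#'
#' @param path CSV path.
#' @return Tibble with `time`, `value` and a `rate` attribute.
#' @export
read_signal_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  meta_path <- paste0(path, ".json")
  rate <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)$rate
  } else {
    1 / stats::median(diff(df$time))
  }
  structure(as_tibble(df), rate = rate)
}
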