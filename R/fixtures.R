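#' Named benchmark scenarios
#'
#' Ground-truth-annotated synthetic records for the canonical multi-target
#' situations: two targets with constant rates (0.2 and 0.37 Hz), two
#' targets breathing alternately (one holds breath for half the record),
#' two targets with ramping rates (0.2 to 0.3 Hz up, 0.5 to 0.4 Hz down,
#' over 30 s), three targets with constant rates (0.12, 0.34, 0.45 Hz),
#' and the plain 1-D two-tone signal (0.2 + 0.35 Hz).  Radar scenarios
#' place all targets at 1.5 m with distinct chest amplitudes, moderate
#' static clutter, and 10 dB SNR white noise.
#'
#' @param scenario One of `"two_constant"`, `"two_piecewise"`,
#'   `"two_timevarying"`, `"three_constant"`, `"sim_two_tone"`.
#' @param seed Integer seed (clutter and noise).
#' @return List: `targets` (or `rates`), `config`, `clutter`,
#'   `suggested_k`, `duration`, and a `truth` tibble of per-target rate
#'   end-points.
#' @export
scenario_spec <- function(scenario, seed = 1) {
  valid <- c("two_constant", "two_piecewise", "two_timevarying",
             "three_constant", "sim_two_tone")
  if (!scenario %in% valid) {
    abort(paste0("unknown scenario `", scenario, "`; valid scenarios: ",
                 paste(valid, collapse = ", ")))
  }
  clut <- clutter_spec(amplitude = 0.5, snr_db = 10, seed = seed)
  ramp <- function(t0, f0, t1, f1) {
    data.frame(time_s = c(t0, t1), rate_hz = c(f0, f1))
  }
  onoff <- function(on_start, on_end) {
    # ~0.5 s physiological ramps instead of hard discontinuities
    data.frame(time_s = c(on_start - 0.25, on_start + 0.25,
                          on_end - 0.25, on_end + 0.25),
               value = c(0, 1, 1, 0))
  }
  switch(scenario,
    two_constant = list(
      scenario = scenario,
      targets = list(
        target_spec(1.5, rate = 0.2, amplitude_m = 0.005, label = "A"),
        target_spec(1.5, rate = 0.37, amplitude_m = 0.004, label = "B")),
      config = radar_config(n_slow = 7630), clutter = clut,
      suggested_k = 3, duration = 50,
      truth = tibble(target = c("A", "B"), rate_start_hz = c(0.2, 0.37),
                     rate_end_hz = c(0.2, 0.37))),
    two_piecewise = list(
      scenario = scenario,
      targets = list(
        target_spec(1.5, rate = 1 / 3, amplitude_m = 0.005,
                    amplitude_schedule = onoff(-1, 25), label = "A"),
        target_spec(1.5, rate = 0.2, amplitude_m = 0.004,
                    amplitude_schedule = onoff(25, 51), label = "B")),
      config = radar_config(n_slow = 7630), clutter = clut,
      suggested_k = 3, duration = 50,
      truth = tibble(target = c("A", "B"),
                     rate_start_hz = c(1 / 3, 0.2),
                     rate_end_hz = c(1 / 3, 0.2),
                     active_s = c("0-25", "25-50"))),
    two_timevarying = list(
      scenario = scenario,
      targets = list(
        target_spec(1.5, rate = ramp(0, 0.2, 30, 0.3), amplitude_m = 0.005,
                    label = "A"),
        target_spec(1.5, rate = ramp(0, 0.5, 30, 0.4), amplitude_m = 0.004,
                    label = "B")),
      config = radar_config(n_slow = 4578), clutter = clut,
      suggested_k = 3, duration = 30,
      truth = tibble(target = c("A", "B"), rate_start_hz = c(0.2, 0.5),
                     rate_end_hz = c(0.3, 0.4))),
    three_constant = list(
      scenario = scenario,
      targets = list(
        target_spec(1.5, rate = 0.12, amplitude_m = 0.005, label = "A"),
        target_spec(1.5, rate = 0.34, amplitude_m = 0.0045, label = "B"),
        target_spec(1.5, rate = 0.45, amplitude_m = 0.004, label = "C")),
      config = radar_config(n_slow = 7630), clutter = clut,
      suggested_k = 4, duration = 50,
      truth = tibble(target = c("A", "B", "C"),
                     rate_start_hz = c(0.12, 0.34, 0.45),
                     rate_end_hz = c(0.12, 0.34, 0.45))),
    sim_two_tone = list(
      scenario = scenario, rates = c(0.2, 0.35), duration = 50,
      rate = 152.6, snr_db = NULL, seed = seed, suggested_k = 2,
      truth = tibble(target = c("A", "B"), rate_start_hz = c(0.2, 0.35),
                     rate_end_hz = c(0.2, 0.35)))
  )
}

#' Write a benchmark scenario to disk
#'
#' Generates the scenario named by [scenario_spec()] and writes either a
#' radar matrix CSV (`<scenario>_radar.csv` + `.json` sidecar) or, for
#' `sim_two_tone`, a signal CSV, plus a `<scenario>_truth.json` sidecar
#' with the per-target rate schedules and true range bins.  Identical
#' `scenario` and `seed` reproduce identical files.
#'
#' @param scenario Scenario name, see [scenario_spec()].
#' @param seed Integer seed.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixtures <- function(scenario, seed = 1, dir = tempdir()) {
  spec <- scenario_spec(scenario, seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth_path <- file.path(dir, paste0(scenario, "_truth.json"))
  if (scenario == "sim_two_tone") {
    sig <- simulate_two_tone(spec$rates, spec$duration, spec$rate,
                             snr_db = spec$snr_db, seed = seed)
    data_path <- file.path(dir, paste0(scenario, "_signal.csv"))
    write_signal_csv(sig, data_path)
    truth <- list(scenario = scenario, seed = seed, rates_hz = spec$rates,
                  duration_s = spec$duration, truth = spec$truth,
                  suggested_k = spec$suggested_k)
  } else {
    R <- generate_echo_matrix(spec$config, spec$targets, spec$clutter)
    data_path <- file.path(dir, paste0(scenario, "_radar.csv"))
    write_radar_csv(R, data_path)
    truth <- list(scenario = scenario, seed = seed,
                  targets = attr(R, "truth")$targets,
                  truth = spec$truth, suggested_k = spec$suggested_k,
                  duration_s = spec$duration)
  }
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(data = data_path, truth = truth_path))
}
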