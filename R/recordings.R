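#' Impairment profile of a simulated limb
#'
#' Parameterizes how a simulated limb deviates from ideal minimum-jerk
#' reaching. The identity profile `impairment_profile()` reproduces the
#' reference movement exactly (up to sensing noise).
#'
#' @param speed_scale dimensionless factor in (0, 1] scaling the commanded
#'   mean speed relative to the task reference speed.
#' @param endpoint_jitter_sd SD of the per-movement endpoint miss (m).
#' @param tremor_amplitude amplitude of the sinusoidal tremor component (m).
#' @param tremor_freq tremor frequency (Hz); physiological action tremor in
#'   children sits around 4-7 Hz.
#' @param path_wander_sd SD of the low-pass-filtered (2 Hz) random path
#'   wander (m).
#' @param submovement_count number of corrective submovements appended after
#'   each discrete movement (integer >= 0).
#' @param effort_inefficiency dimensionless factor >= 1 scaling the drive
#'   force the user applies for the same movement.
#' @return a list of class `impairment_profile`.
#' @export
impairment_profile <- function(speed_scale = 1,
                               endpoint_jitter_sd = 0,
                               tremor_amplitude = 0,
                               tremor_freq = 5,
                               path_wander_sd = 0,
                               submovement_count = 0L,
                               effort_inefficiency = 1) {
  if (speed_scale <= 0 || speed_scale > 1)
    stop("`speed_scale` must be in (0, 1]", call. = FALSE)
  vals <- c(endpoint_jitter_sd, tremor_amplitude, tremor_freq,
            path_wander_sd, submovement_count)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("impairment parameters must be finite and non-negative", call. = FALSE)
  if (effort_inefficiency < 1)
    stop("`effort_inefficiency` must be >= 1", call. = FALSE)
  structure(list(speed_scale = speed_scale,
                 endpoint_jitter_sd = endpoint_jitter_sd,
                 tremor_amplitude = tremor_amplitude,
                 tremor_freq = tremor_freq,
                 path_wander_sd = path_wander_sd,
                 submovement_count = as.integer(round(submovement_count)),
                 effort_inefficiency = effort_inefficiency),
            class = "impairment_profile")
}

#' Sensing-chain noise specification
#'
#' Noise model of the device's localization and force sensing: wheel-odometry
#' slip per 10 ms step, optical fixes from the coded working surface at
#' `optical_rate`, and load-cell noise. The manufacturer-grade defaults are a
#' system-level position accuracy of about 0.4 mm and a force accuracy of
#' 0.01 N.
#'
#' @param odometry_slip_sd SD of per-step odometry increment error (m).
#' @param optical_noise_sd SD of optical position fixes (m).
#' @param optical_rate optical fix rate (Hz); at most the 100 Hz sample rate.
#' @param force_noise_sd SD of load-cell force noise per axis (N).
#' @return a list of class `sensor_noise_spec`.
#' @export
sensor_noise_spec <- function(odometry_slip_sd = 5e-5,
                              optical_noise_sd = 4e-4,
                              optical_rate = 25,
                              force_noise_sd = 0.01) {
  if (any(c(odometry_slip_sd, optical_noise_sd, optical_rate, force_noise_sd) < 0))
    stop("noise parameters must be >= 0", call. = FALSE)
  if (optical_rate > 100)
    stop("`optical_rate` cannot exceed the 100 Hz sample rate", call. = FALSE)
  structure(list(odometry_slip_sd = odometry_slip_sd,
                 optical_noise_sd = optical_noise_sd,
                 optical_rate = optical_rate,
                 force_noise_sd = force_noise_sd),
            class = "sensor_noise_spec")
}

#' @rdname sensor_noise_spec
#' @details `zero_noise()` is the all-zero noise specification (ideal
#'   sensing), handy for oracle tests.
#' @export
zero_noise <- function() sensor_noise_spec(0, 0, 25, 0)

#' Trial recording container
#'
#' One participant x limb x task recording of time-stamped planar position and
#' handle-force samples at a nominal 100 Hz. Validity: strictly increasing
#' timestamps, finite values, and force magnitude within the device's 50 N cap.
#'
#' @param participant_id character id.
#' @param limb `"MAS"` (more affected side) or `"LAS"` (less affected side).
#' @param task_id one of the five task ids.
#' @param t,x,y,fx,fy equal-length numeric sample vectors: time (s), position
#'   (m) and handle force (N).
#' @param sample_rate sampling rate (Hz), nominally 100.
#' @return a list of class `trial_recording` with a `samples` data.frame.
#' @export
trial_recording <- function(participant_id, limb, task_id, t, x, y, fx, fy,
                            sample_rate = 100) {
  limb <- match.arg(limb, c("LAS", "MAS"))
  task_id <- match.arg(task_id, task_ids())
  n <- length(t)
  if (n < 1L || any(lengths(list(x, y, fx, fy)) != n))
    stop("sample vectors must be non-empty and of equal length", call. = FALSE)
  if (any(!is.finite(c(t, x, y, fx, fy))))
    stop("trial samples must be finite", call. = FALSE)
  if (n > 1L && any(diff(t) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  fmag <- sqrt(fx^2 + fy^2)
  if (any(fmag > 50 + 1e-9))
    stop("force magnitude exceeds the 50 N device cap", call. = FALSE)
  structure(list(participant_id = as.character(participant_id),
                 limb = limb, task_id = task_id,
                 samples = data.frame(t = t, x = x, y = y, fx = fx, fy = fy),
                 sample_rate = sample_rate),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s / %s / %s: %d samples, %.1f s @ %g Hz\n",
              x$participant_id, x$limb, x$task_id, nrow(x$samples),
              diff(range(x$samples$t)), x$sample_rate))
  invisible(x)
}

#' Write / read a raw trial log CSV
#'
#' The raw-log dialect mirrors the device export: UTF-8 comma-separated with
#' dot decimals, `#`-prefixed key=value header lines
#' (`participant_id`, `limb`, `task`, `sample_rate_hz`) followed by the
#' columns `t_s,x_m,y_m,fx_n,fy_n`.
#'
#' @param rec a [trial_recording()].
#' @param path file path.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv`
#'   returns a [trial_recording()].
#' @export
write_trial_csv <- function(rec, path) {
  stopifnot(inherits(rec, "trial_recording"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# participant_id=%s", rec$participant_id),
               sprintf("# limb=%s", rec$limb),
               sprintf("# task=%s", rec$task_id),
               sprintf("# sample_rate_hz=%g", rec$sample_rate),
               "t_s,x_m,y_m,fx_n,fy_n"), con)
  s <- rec$samples
  writeLines(sprintf("%.6f,%.8f,%.8f,%.6f,%.6f", s$t, s$x, s$y, s$fx, s$fy), con)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- stats::setNames(as.list(vals), keys)
  body <- lines[!grepl("^#", lines)]
  dat <- utils::read.csv(text = paste(body, collapse = "\n"))
  trial_recording(meta$participant_id, meta$limb, meta$task,
                  t = dat$t_s, x = dat$x_m, y = dat$y_m,
                  fx = dat$fx_n, fy = dat$fy_n,
                  sample_rate = as.numeric(meta$sample_rate_hz))
}
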