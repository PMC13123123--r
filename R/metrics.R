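# Central-difference velocities from timestamped samples (one-sided at ends).
sample_velocity <- function(t, x, y) {
  n <- length(t)
  if (n < 2L) stop("at least two samples are required", call. = FALSE)
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  vx <- c((x[2] - x[1]) / (t[2] - t[1]),
          if (n > 2L) (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]),
          (x[n] - x[n - 1]) / (t[n] - t[n - 1]))
  vy <- c((y[2] - y[1]) / (t[2] - t[1]),
          if (n > 2L) (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]),
          (y[n] - y[n - 1]) / (t[n] - t[n - 1]))
  cbind(vx, vy)
}

# Speed below which the direction of motion is undefined and work integrands
# are set to zero.
STALL_SPEED <- 1e-4

#' Covered area of a trial
#'
#' Total area covered by the movement, including both correct and incorrect
#' movements: each sample is assigned to one of 120 angular bins of width
#' `2*pi/120` around the workspace centre, and the area is
#' `sum_k 0.5 * r_max(theta_k)^2 * delta_theta` over the per-bin maximum radii.
#' Empty bins contribute zero; all samples coincident with the centre give 0.
#'
#' @param rec a [trial_recording()].
#' @param center workspace centre, length-2 numeric (m).
#' @return covered area (m^2).
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 721)[-721]
#' rec <- trial_recording("p", "LAS", "small_rom", t = seq_along(th) / 100,
#'                        x = 0.1 * cos(th), y = 0.1 * sin(th),
#'                        fx = 0 * th, fy = 0 * th)
#' compute_area(rec, c(0, 0))  # pi * 0.1^2: every bin sees the full radius
compute_area <- function(rec, center = c(0, 0)) {
  stopifnot(inherits(rec, "trial_recording"))
  s <- rec$samples
  if (nrow(s) < 2L) stop("at least two samples are required", call. = FALSE)
  dx <- s$x - center[1]
  dy <- s$y - center[2]
  r <- sqrt(dx^2 + dy^2)
  dth <- 2 * pi / 120
  theta <- atan2(dy, dx) %% (2 * pi)
  bin <- pmin(floor(theta / dth), 119) + 1L
  rmax <- numeric(120)
  agg <- tapply(r, bin, max)
  rmax[as.integer(names(agg))] <- agg
  sum(0.5 * rmax^2 * dth)
}

#' Total and useful mechanical work of a trial
#'
#' The effort the user spends pushing the manipulandum. Total work integrates
#' the absolute projection of the handle force on the direction of motion
#' times the speed, `integral |F . u_hat| * ||u|| dt`; useful work integrates
#' the force component along the reference-path tangent times the tangential
#' speed, `integral (F . t_hat) * ||u_tan|| dt`, where the tangent is taken at
#' the nearest path point. In free mode (no reference path) the tangent is
#' the direction of motion itself, so useful work is the signed work along the
#' movement. Velocities come from central finite differences, integration is
#' trapezoidal on the sample grid, and samples slower than 1e-4 m/s (direction
#' undefined) contribute zero.
#'
#' @param rec a [trial_recording()].
#' @param path a [reference_path()], or `NULL` for free-mode tasks.
#' @param path_index optional precomputed nearest-path-point indices (one per
#'   sample), to avoid repeating the search when several indices share it.
#' @return named numeric: `work_total` and `work_useful` (J).
#' @export
compute_work <- function(rec, path = NULL, path_index = NULL) {
  stopifnot(inherits(rec, "trial_recording"))
  s <- rec$samples
  if (nrow(s) < 2L) stop("at least two samples are required", call. = FALSE)
  vel <- sample_velocity(s$t, s$x, s$y)
  speed <- sqrt(vel[, 1]^2 + vel[, 2]^2)
  moving <- speed >= STALL_SPEED
  # |F . u_hat| ||u|| = |F . u|
  g_tot <- ifelse(moving, abs(s$fx * vel[, 1] + s$fy * vel[, 2]), 0)
  if (is.null(path)) {
    g_use <- ifelse(moving, s$fx * vel[, 1] + s$fy * vel[, 2], 0)
  } else {
    idx <- if (is.null(path_index)) nearest_path_index(s$x, s$y, path) else path_index
    tg <- path_tangents(path)[idx, , drop = FALSE]
    u_tan <- vel[, 1] * tg[, 1] + vel[, 2] * tg[, 2]
    f_tan <- s$fx * tg[, 1] + s$fy * tg[, 2]
    g_use <- ifelse(moving, f_tan * abs(u_tan), 0)
  }
  trap <- function(g) sum(diff(s$t) * (g[-length(g)] + g[-1]) / 2)
  c(work_total = trap(g_tot), work_useful = trap(g_use))
}

#' Normalized average velocity of a trial
#'
#' Mean sample speed as a percentage of the task reference speed.
#'
#' @param rec a [trial_recording()].
#' @param reference_speed task reference speed (m/s), > 0.
#' @return normalized velocity (%).
#' @export
compute_velocity <- function(rec, reference_speed) {
  stopifnot(inherits(rec, "trial_recording"))
  stopifnot_scalar(reference_speed, "reference_speed", positive = TRUE)
  s <- rec$samples
  vel <- sample_velocity(s$t, s$x, s$y)
  100 * mean(sqrt(vel[, 1]^2 + vel[, 2]^2)) / reference_speed
}

#' Accuracy error of a trial
#'
#' Average distance from the ideal trajectory: for every sample, the distance
#' to the nearest point of the reference-path polyline (resolution at most
#' 1 mm); the mean over all samples is reported in millimetres. The
#' correspondence is geometric (nearest point), not time-indexed, because the
#' tasks are self-paced.
#'
#' @param rec a [trial_recording()].
#' @param path a [reference_path()].
#' @param path_index optional precomputed nearest-path-point indices.
#' @return mean distance to the ideal trajectory (mm).
#' @export
compute_accuracy_error <- function(rec, path, path_index = NULL) {
  stopifnot(inherits(rec, "trial_recording"))
  if (!inherits(path, "reference_path") || length(path$x) == 0L)
    stop("`path` must be a non-empty reference_path", call. = FALSE)
  s <- rec$samples
  if (nrow(s) < 1L) stop("empty recording", call. = FALSE)
  idx <- if (is.null(path_index)) nearest_path_index(s$x, s$y, path) else path_index
  1000 * mean(sqrt((path$x[idx] - s$x)^2 + (path$y[idx] - s$y)^2))
}

#' Completion time of a trial
#'
#' @param rec a [trial_recording()].
#' @return elapsed time from first to last sample (s).
#' @export
compute_time <- function(rec) {
  stopifnot(inherits(rec, "trial_recording"))
  s <- rec$samples
  if (nrow(s) < 2L) stop("at least two samples are required", call. = FALSE)
  s$t[nrow(s)] - s$t[1]
}

#' Per-trial summary report of the device indices
#'
#' Computes exactly the indices recorded for the given task: covered area for
#' the ROM tasks only, accuracy error for the constrained (eight and coins)
#' tasks only, and time, work and normalized velocity for every task. Time is
#' rendered both in seconds and minutes; both the total and the useful work
#' integrals are reported.
#'
#' @param rec a [trial_recording()].
#' @param task the matching [build_task()] specification.
#' @param v_max normalization speed for the velocity index; defaults to the
#'   task reference speed (falling back to the 0.8 m/s device cap if the task
#'   carries none).
#' @return a one-row `data.frame` of class `metric_report` with columns
#'   `participant_id, limb, task, area_m2, time_s, time_min, work_total_j,
#'   work_useful_j, velocity_pct, accuracy_error_mm` (`NA` where the index is
#'   not recorded for the task).
#' @export
build_report <- function(rec, task, v_max = NULL) {
  stopifnot(inherits(rec, "trial_recording"), inherits(task, "task_spec"))
  if (rec$task_id != task$task_id)
    stop(sprintf("recording is for task '%s' but spec is '%s'",
                 rec$task_id, task$task_id), call. = FALSE)
  if (is.null(v_max))
    v_max <- if (is.finite(task$reference_speed)) task$reference_speed else 0.8
  is_rom <- task$task_id %in% rom_tasks()
  idx <- if (is_rom) NULL else
    nearest_path_index(rec$samples$x, rec$samples$y, task$reference_path)
  w <- compute_work(rec, if (is_rom) NULL else task$reference_path, path_index = idx)
  time_s <- compute_time(rec)
  out <- data.frame(
    participant_id = rec$participant_id,
    limb = rec$limb,
    task = rec$task_id,
    area_m2 = if (is_rom) compute_area(rec, task$center) else NA_real_,
    time_s = time_s,
    time_min = time_s / 60,
    work_total_j = unname(w["work_total"]),
    work_useful_j = unname(w["work_useful"]),
    velocity_pct = compute_velocity(rec, v_max),
    accuracy_error_mm = if (is_rom) NA_real_ else
      compute_accuracy_error(rec, task$reference_path, path_index = idx),
    stringsAsFactors = FALSE)
  class(out) <- c("metric_report", "data.frame")
  out
}

#' Write / read per-trial metric reports as CSV
#'
#' One row per trial with the columns of [build_report()]; indices that the
#' task does not record are written as empty cells.
#'
#' @param reports a `data.frame` of stacked [build_report()] rows.
#' @param path file path.
#' @return `write_reports_csv` returns `path` invisibly; `read_reports_csv`
#'   returns the reports `data.frame`.
#' @export
write_reports_csv <- function(reports, path) {
  utils::write.csv(reports, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_reports_csv
#' @export
read_reports_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(participant_id = "character"))
  class(out) <- c("metric_report", "data.frame")
  out
}

#' Compute the metric table of a set of trials
#'
#' @param trials list of [trial_recording()]s.
#' @param workspace the [workspace_config()] used to build the tasks.
#' @return a `data.frame` with one [build_report()] row per trial.
#' @export
metrics_table <- function(trials, workspace = workspace_config()) {
  specs <- lapply(stats::setNames(task_ids(), task_ids()),
                  build_task, workspace = workspace)
  rows <- lapply(trials, function(rec) build_report(rec, specs[[rec$task_id]]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
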