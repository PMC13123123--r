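#' Resistive guidance force toward the reference path
#'
#' On constrained tasks the robot opposes deviation from the ideal trajectory
#' with a force directed from the current position toward the nearest path
#' point, of magnitude `k1 * d + k2 * d^2` where `d` is the distance to the
#' path, clipped at the device's 50 N force cap.
#'
#' @param position n x 2 matrix (or length-2 vector) of planar positions (m).
#' @param path a [reference_path()].
#' @param gains length-2 numeric: linear (N/m) and quadratic (N/m^2) gains,
#'   both >= 0.
#' @return an n x 2 matrix of guidance forces (N).
#' @export
#' @examples
#' p <- build_task("small_eight")$reference_path
#' guidance_force(c(p$x[1], p$y[1]), p, c(40, 400))  # on the path: zero force
guidance_force <- function(position, path, gains) {
  if (!inherits(path, "reference_path") || length(path$x) == 0L)
    stop("`path` must be a non-empty reference_path", call. = FALSE)
  if (length(gains) != 2L || any(gains < 0))
    stop("`gains` must be two non-negative numbers", call. = FALSE)
  pos <- if (is.null(dim(position))) matrix(position, ncol = 2) else as.matrix(position)
  idx <- nearest_path_index(pos[, 1], pos[, 2], path)
  dx <- path$x[idx] - pos[, 1]
  dy <- path$y[idx] - pos[, 2]
  d <- sqrt(dx^2 + dy^2)
  mag <- pmin(gains[1] * d + gains[2] * d^2, 50)
  scale <- ifelse(d > 0, mag / d, 0)
  cbind(dx * scale, dy * scale)
}

# Minimum-jerk position profile on [0, 1]: 10 tau^3 - 15 tau^4 + 6 tau^5.
minjerk_s <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

# One minimum-jerk point-to-point segment sampled at dt; returns the matrix of
# positions excluding the start point (duration quantized to the sample grid).
minjerk_segment <- function(from, to, duration, dt) {
  n <- max(2L, as.integer(round(duration / dt)))
  s <- minjerk_s(seq_len(n) / n)
  cbind(from[1] + (to[1] - from[1]) * s,
        from[2] + (to[2] - from[2]) * s)
}

# Commanded (pre-perturbation) trajectory for a waypoint task (ROM / coins):
# minimum-jerk segments between consecutive waypoints, endpoint jitter on
# every arrival, optional corrective submovements, and a short dwell at each
# waypoint. Returns positions and total scheduled duration (s).
command_waypoints <- function(task, profile, dt) {
  way <- task$waypoints
  v <- task$reference_speed * profile$speed_scale
  dwell_n <- 8L
  parts <- list(matrix(way[1, ], nrow = 1))
  cur <- way[1, ]
  sched <- 0
  for (k in 2:nrow(way)) {
    target <- way[k, ]
    d0 <- sqrt(sum((target - cur)^2))
    dir <- if (d0 > 0) (target - cur) / d0 else c(0, 0)
    # hypermetria: impaired reaches overshoot the target along the movement
    # direction, in proportion to the endpoint noise level
    aim <- target + jitter_draw(2, profile$endpoint_jitter_sd) +
      dir * 0.8 * profile$endpoint_jitter_sd
    d <- sqrt(sum((aim - cur)^2))
    if (!all(is.finite(aim))) stop("unreachable geometry", call. = FALSE)
    dur <- max(d / v, 0.2)
    seg <- minjerk_segment(cur, aim, dur, dt)
    parts[[length(parts) + 1L]] <- seg
    cur <- aim
    sched <- sched + nrow(seg) * dt
    if (profile$submovement_count > 0L) {
      for (j in seq_len(profile$submovement_count)) {
        hop_aim <- target + jitter_draw(2, 0.3 * profile$endpoint_jitter_sd + 0.002)
        hd <- sqrt(sum((hop_aim - cur)^2))
        hop <- minjerk_segment(cur, hop_aim, max(hd / v, 0.15), dt)
        parts[[length(parts) + 1L]] <- hop
        cur <- hop_aim
        sched <- sched + nrow(hop) * dt
      }
    }
    parts[[length(parts) + 1L]] <- matrix(rep(cur, each = dwell_n), ncol = 2)
    sched <- sched + dwell_n * dt
  }
  list(pos = do.call(rbind, parts), scheduled = sched)
}

# Commanded trajectory for the figure-eight: per-lap minimum-jerk arc-length
# profile along the closed reference path. Endpoint jitter does not apply:
# the path is tracked continuously under visual feedback and resistive
# guidance, so sustained offsets do not persist; deviation comes from the
# tremor and wander perturbations.
command_eight <- function(task, profile, dt) {
  path <- task$reference_path
  L <- path$length
  v <- task$reference_speed * profile$speed_scale
  lap_dur <- L / v
  pos <- matrix(c(path$x[1], path$y[1]), nrow = 1)
  sched <- 0
  for (lap in seq_len(task$n_movements)) {
    n <- max(2L, as.integer(round(lap_dur / dt)))
    s <- L * minjerk_s(seq_len(n) / n)
    pts <- path_point_at(path, s)
    pos <- rbind(pos, pts)
    sched <- sched + n * dt
  }
  list(pos = pos, scheduled = sched)
}

# Endpoint-miss draw: Gaussian truncated at +/- 1.5 SD. Visual feedback and
# (on constrained tasks) the resistive guidance bound how far an endpoint or
# tracked path can drift, so gross misses do not occur.
jitter_draw <- function(k, sd) {
  if (sd <= 0) return(numeric(k))
  z <- stats::qnorm(stats::runif(k, stats::pnorm(-1.5), stats::pnorm(1.5)))
  sd * z
}

# Low-pass filtered (two cascaded one-pole stages at cutoff_hz) standard-
# normal noise rescaled to unit stationary SD; used for the path-wander
# perturbation. The cascade's stationary variance for unit white input is
# (1-a)^4 (1+a^2) / (1-a^2)^3.
lowpass_noise <- function(n, dt, cutoff_hz = 2) {
  a <- exp(-2 * pi * cutoff_hz * dt)
  e <- (1 - a) * stats::rnorm(n)
  w <- stats::filter(e, a, method = "recursive")
  w <- stats::filter((1 - a) * w, a, method = "recursive")
  as.numeric(w) / sqrt((1 - a)^4 * (1 + a^2) / (1 - a^2)^3)
}

#' Simulate one trial on the device
#'
#' Generates the full sensing-chain output for one participant x limb x task:
#' minimum-jerk movements scaled by the profile's speed factor, perturbed by a
#' 4-7 Hz tremor sinusoid, low-pass (2 Hz) Gaussian path wander, endpoint
#' jitter and optional corrective submovements; speed is clipped at the
#' device's 0.8 m/s cap. The force channel models the user's drive force
#' (aligned with the velocity, scaled by `effort_inefficiency`) minus the
#' resistive guidance force on constrained tasks, plus load-cell noise, capped
#' at 50 N. Positions are passed through the odometry + optical fusion chain
#' ([localize_fuse()]) unless all noise terms are zero.
#'
#' The same `(task, profile, noise, seed)` always yields an identical
#' recording.
#'
#' @param task a [build_task()] specification.
#' @param profile an [impairment_profile()].
#' @param noise a [sensor_noise_spec()].
#' @param seed non-negative integer seed.
#' @param participant_id,limb identifiers stored in the recording.
#' @param drive_gain drive-force coefficient (N per m/s of commanded speed).
#' @return a [trial_recording()]; attribute `scheduled_duration` holds the
#'   movement schedule on the sample grid (s).
#' @export
#' @examples
#' tk <- build_task("small_eight")
#' rec <- simulate_trial(tk, impairment_profile(), zero_noise(), seed = 1)
#' compute_accuracy_error(rec, tk$reference_path)  # < 0.5 mm: ideal tracking
simulate_trial <- function(task, profile, noise = sensor_noise_spec(), seed,
                           participant_id = "sim", limb = "LAS",
                           drive_gain = 40) {
  stopifnot(inherits(task, "task_spec"), inherits(profile, "impairment_profile"),
            inherits(noise, "sensor_noise_spec"))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stop("`seed` must be a single non-negative integer", call. = FALSE)
  dt <- 0.01
  with_seed(seed, {
    cmd <- if (task$task_id %in% c("small_eight", "large_eight"))
      command_eight(task, profile, dt) else command_waypoints(task, profile, dt)
    pos <- cmd$pos
    n <- nrow(pos)
    t <- (seq_len(n) - 1L) * dt

    # tremor sinusoid with random per-axis phases
    if (profile$tremor_amplitude > 0) {
      ph <- stats::runif(2, 0, 2 * pi)
      pos[, 1] <- pos[, 1] + profile$tremor_amplitude * sin(2 * pi * profile$tremor_freq * t + ph[1])
      pos[, 2] <- pos[, 2] + profile$tremor_amplitude * sin(2 * pi * profile$tremor_freq * t + ph[2])
    }
    # low-pass filtered path wander
    if (profile$path_wander_sd > 0) {
      pos[, 1] <- pos[, 1] + profile$path_wander_sd * lowpass_noise(n, dt)
      pos[, 2] <- pos[, 2] + profile$path_wander_sd * lowpass_noise(n, dt)
    }
    # controller speed cap: rescale any over-limit increment, re-integrate
    inc <- diff(pos)
    spd <- sqrt(inc[, 1]^2 + inc[, 2]^2) / dt
    over <- spd > 0.8
    if (any(over)) {
      f <- 0.8 * dt / (spd[over] * dt)
      inc[over, ] <- inc[over, ] * f
      pos <- rbind(pos[1, , drop = FALSE],
                   cbind(pos[1, 1] + cumsum(inc[, 1]),
                         pos[1, 2] + cumsum(inc[, 2])))
    }

    # true velocity (central differences) drives the force model
    vel <- central_diff(pos, dt)
    f_cell <- drive_gain * profile$effort_inefficiency * vel
    if (!is.null(task$guidance_gains)) {
      f_guid <- guidance_force(pos, task$reference_path, task$guidance_gains)
      f_cell <- f_cell - f_guid
    }
    if (noise$force_noise_sd > 0)
      f_cell <- f_cell + matrix(stats::rnorm(2 * n, 0, noise$force_noise_sd), n, 2)
    fmag <- sqrt(f_cell[, 1]^2 + f_cell[, 2]^2)
    cap <- fmag > 50
    if (any(cap)) f_cell[cap, ] <- f_cell[cap, ] * (50 / fmag[cap])

    # sensing chain: odometry + optical fusion, unless noiseless
    if (noise$odometry_slip_sd > 0 || noise$optical_noise_sd > 0) {
      inc <- diff(pos)
      m <- nrow(inc)
      odo <- inc + matrix(stats::rnorm(2 * m, 0, noise$odometry_slip_sd), m, 2)
      every <- max(1L, as.integer(round(100 / noise$optical_rate)))
      opt <- matrix(NA_real_, m, 2)
      fix <- seq(every, m, by = every)
      opt[fix, ] <- pos[fix + 1L, ] +
        matrix(stats::rnorm(2 * length(fix), 0, noise$optical_noise_sd), length(fix), 2)
      fused <- localize_fuse(odo, opt, noise, origin = pos[1, ])
      rec_pos <- rbind(pos[1, , drop = FALSE], fused$estimate)
      # the firmware reports controller-limited velocity: re-clip the
      # recorded stream, whose sensing noise can nudge a capped speed over
      rinc <- diff(rec_pos)
      rspd <- sqrt(rinc[, 1]^2 + rinc[, 2]^2) / dt
      rover <- rspd > 0.8
      if (any(rover)) {
        rinc[rover, ] <- rinc[rover, ] * (0.8 / rspd[rover])
        rec_pos <- rbind(rec_pos[1, , drop = FALSE],
                         cbind(rec_pos[1, 1] + cumsum(rinc[, 1]),
                               rec_pos[1, 2] + cumsum(rinc[, 2])))
      }
    } else rec_pos <- pos

    rec <- trial_recording(participant_id, limb, task$task_id,
                           t = t, x = rec_pos[, 1], y = rec_pos[, 2],
                           fx = f_cell[, 1], fy = f_cell[, 2],
                           sample_rate = 1 / dt)
    attr(rec, "scheduled_duration") <- cmd$scheduled
    rec
  })
}

# Central-difference planar velocity (one-sided at the ends).
central_diff <- function(pos, dt) {
  n <- nrow(pos)
  if (n < 2L) return(matrix(0, n, 2))
  vx <- c(pos[2, 1] - pos[1, 1],
          if (n > 2L) (pos[3:n, 1] - pos[1:(n - 2), 1]) / 2,
          pos[n, 1] - pos[n - 1, 1]) / dt
  vy <- c(pos[2, 2] - pos[1, 2],
          if (n > 2L) (pos[3:n, 2] - pos[1:(n - 2), 2]) / 2,
          pos[n, 2] - pos[n - 1, 2]) / dt
  cbind(vx, vy)
}
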