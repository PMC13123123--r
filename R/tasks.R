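#' Workspace geometry configuration
#'
#' Geometry of the planar workspace used to construct the five assessment
#' tasks. The device's published description does not fix these dimensions, so
#' they are free parameters with tabletop-plausible defaults (metres).
#'
#' @param center workspace centre, length-2 numeric (m).
#' @param small_rom_radius,large_rom_radius radial target distance for the
#'   small / large centre-out reaching tasks (m).
#' @param eight_half_width_small,eight_half_width_large half-width of the
#'   figure-eight (lemniscate of Gerono) for the small / large tracking tasks (m).
#' @param coin_arc_radius radius of the arc on which the five coins sit (m).
#' @param coin_drop_offset extra radial distance of the drop zones (m).
#' @param path_resolution arc-length spacing of reference-path polylines (m);
#'   must be at most 1 mm.
#' @param reference_speeds named numeric vector of task reference speeds (m/s).
#' @param guidance_gains length-2 numeric: linear (N/m) and quadratic (N/m^2)
#'   resistive guidance gains for the constrained tasks.
#' @return a list of class `workspace_config`.
#' @export
workspace_config <- function(center = c(0, 0),
                             small_rom_radius = 0.08,
                             large_rom_radius = 0.14,
                             eight_half_width_small = 0.06,
                             eight_half_width_large = 0.12,
                             coin_arc_radius = 0.10,
                             coin_drop_offset = 0.06,
                             path_resolution = 0.001,
                             reference_speeds = c(small_rom = 0.10,
                                                  large_rom = 0.10,
                                                  small_eight = 0.08,
                                                  large_eight = 0.08,
                                                  coins = 0.08),
                             guidance_gains = c(linear = 40, quadratic = 400)) {
  if (small_rom_radius <= 0 || large_rom_radius <= 0)
    stop("task radii must be positive", call. = FALSE)
  if (small_rom_radius >= large_rom_radius)
    stop("small ROM radius must be strictly smaller than large ROM radius", call. = FALSE)
  if (path_resolution <= 0 || path_resolution > 0.001)
    stop("`path_resolution` must be in (0, 0.001] m", call. = FALSE)
  if (any(guidance_gains < 0)) stop("guidance gains must be >= 0", call. = FALSE)
  structure(list(center = as.numeric(center),
                 small_rom_radius = small_rom_radius,
                 large_rom_radius = large_rom_radius,
                 eight_half_width_small = eight_half_width_small,
                 eight_half_width_large = eight_half_width_large,
                 coin_arc_radius = coin_arc_radius,
                 coin_drop_offset = coin_drop_offset,
                 path_resolution = path_resolution,
                 reference_speeds = reference_speeds,
                 guidance_gains = guidance_gains),
            class = "workspace_config")
}

task_ids <- function() c("small_rom", "large_rom", "small_eight", "large_eight", "coins")

rom_tasks <- function() c("small_rom", "large_rom")
constrained_tasks <- function() c("small_eight", "large_eight", "coins")

#' Construct a reference path from a planar polyline
#'
#' Resamples the polyline at fixed arc-length resolution (at most 1 mm between
#' consecutive points); the resampled points are the ideal-trajectory
#' coordinates used by the accuracy-error index.
#'
#' @param x,y coordinates of the polyline vertices (m).
#' @param closed logical; does the path loop back onto its first point?
#' @param resolution arc-length spacing of the resampled polyline (m).
#' @return a list of class `reference_path` with fields `x`, `y`, `closed`,
#'   `length` (total arc length, m) and `resolution`.
#' @export
reference_path <- function(x, y, closed = FALSE, resolution = 0.001) {
  if (length(x) < 2L || length(x) != length(y))
    stop("a reference path needs at least two vertices", call. = FALSE)
  if (closed && (x[1] != x[length(x)] || y[1] != y[length(y)])) {
    x <- c(x, x[1]); y <- c(y, y[1])
  }
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  keep <- c(TRUE, seg > 0)
  x <- x[keep]; y <- y[keep]
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate reference path (zero length)", call. = FALSE)
  grid <- unique(c(seq(0, total, by = resolution), total))
  structure(list(x = stats::approx(s, x, xout = grid)$y,
                 y = stats::approx(s, y, xout = grid)$y,
                 closed = closed,
                 length = total,
                 resolution = resolution),
            class = "reference_path")
}

#' @export
print.reference_path <- function(x, ...) {
  cat(sprintf("<reference_path> %d points, %.3f m%s\n",
              length(x$x), x$length, if (x$closed) ", closed" else ""))
  invisible(x)
}

# Arc-length interpolation along a reference path; s may exceed length for
# closed paths (wraps around).
path_point_at <- function(path, s) {
  grid <- seq(0, path$length, length.out = length(path$x))
  if (path$closed) s <- s %% path$length
  s <- clamp(s, 0, path$length)
  cbind(stats::approx(grid, path$x, xout = s)$y,
        stats::approx(grid, path$y, xout = s)$y)
}

# Index of the nearest polyline point for each sample. Coarse-to-fine search
# on long polylines (decimated scan, then a local window around the coarse
# minimum); exhaustive chunked scan on short ones. Where two path branches
# compete at nearly equal distance (the lemniscate self-crossing) the coarse
# stage can settle on the farther branch, so the returned distance can exceed
# the true minimum by at most half the coarse spacing (<= 5 mm at 1 mm path
# resolution) for isolated samples; trial-level means are unaffected at the
# sub-0.1 mm level. Chunked to bound memory.
nearest_path_index <- function(x, y, path, chunk = 4096L) {
  n <- length(x)
  idx <- integer(n)
  px <- path$x; py <- path$y
  np <- length(px)
  stride <- clamp(as.integer(sqrt(np / 2)), 5L, 10L)
  win <- stride + 2L
  coarse <- np > 4L * stride
  if (coarse) {
    ci <- seq(1L, np, by = stride)
    offs <- -win:win
    # squared distance via |p - q|^2 = |p|^2 - 2 p.q + |q|^2; the constant
    # per-row |p|^2 term is irrelevant to the argmin
    cb <- rbind(px[ci], py[ci])
    cn <- px[ci]^2 + py[ci]^2
  }
  start <- 1L
  while (start <= n) {
    s <- start:min(start + chunk - 1L, n)
    if (coarse) {
      d2c <- cbind(x[s], y[s]) %*% (-2 * cb)
      d2c <- sweep(d2c, 2L, cn, "+")
      best <- ci[max.col(-d2c, ties.method = "first")]
      cand <- outer(best, offs, "+")
      cand <- if (path$closed) ((cand - 1L) %% np) + 1L else pmin(pmax(cand, 1L), np)
      d2 <- (x[s] - matrix(px[cand], nrow = length(s)))^2 +
            (y[s] - matrix(py[cand], nrow = length(s)))^2
      pick <- max.col(-d2, ties.method = "first")
      idx[s] <- cand[cbind(seq_along(s), pick)]
    } else {
      d2 <- outer(x[s], px, "-")^2 + outer(y[s], py, "-")^2
      idx[s] <- max.col(-d2, ties.method = "first")
    }
    start <- s[length(s)] + 1L
  }
  idx
}

# Unit tangents of the polyline (central differences; wraps if closed).
path_tangents <- function(path) {
  x <- path$x; y <- path$y; n <- length(x)
  if (path$closed) {
    # first and last resampled points coincide; wrap through the duplicate
    xp <- c(x[n - 1L], x, x[2L]); yp <- c(y[n - 1L], y, y[2L])
    tx <- xp[3:(n + 2)] - xp[1:n]
    ty <- yp[3:(n + 2)] - yp[1:n]
  } else {
    tx <- c(x[2] - x[1], x[3:n] - x[1:(n - 2)], x[n] - x[n - 1])
    ty <- c(y[2] - y[1], y[3:n] - y[1:(n - 2)], y[n] - y[n - 1])
  }
  nrm <- sqrt(tx^2 + ty^2)
  nrm[nrm == 0] <- 1
  cbind(tx / nrm, ty / nrm)
}

# Lemniscate of Gerono centred on `center`: x = a cos t, y = (a/2) sin 2t,
# started at the centre crossing (t = pi/2) so trials begin at the workspace
# centre.
lemniscate_points <- function(center, a, n = 2000L) {
  t <- seq(pi / 2, pi / 2 + 2 * pi, length.out = n)
  cbind(center[1] + a * cos(t), center[2] + (a / 2) * sin(2 * t))
}

#' Build the specification of one assessment task
#'
#' Constructs targets, the ideal reference path, movement count, reference
#' speed and (for constrained tasks) resistive guidance gains for one of the
#' five tasks: centre-out reaching to 8 radial targets at a small or large
#' radius (`small_rom`, `large_rom`, free mode, 16 clockwise movements),
#' constrained figure-eight tracking (`small_eight`, `large_eight`) and the
#' five-coin transport task (`coins`).
#'
#' ROM targets are spaced every 45 degrees, enumerated clockwise starting from
#' the 12-o'clock direction, and the reference path concatenates the
#' out-and-back centre-target segments.
#'
#' @param task_id one of `"small_rom"`, `"large_rom"`, `"small_eight"`,
#'   `"large_eight"`, `"coins"`.
#' @param workspace a [workspace_config()].
#' @return a list of class `task_spec` with fields `task_id`, `targets`
#'   (matrix of waypoints, m), `waypoints` (full ordered waypoint sequence the
#'   movement passes through, including centre returns), `reference_path`,
#'   `n_movements`, `reference_speed`, `guidance_gains` (`NULL` in free mode)
#'   and `center`.
#' @export
#' @examples
#' tk <- build_task("small_rom")
#' nrow(tk$targets)   # 8 radial targets
#' tk$n_movements     # 16 movements (out and back per target)
build_task <- function(task_id, workspace = workspace_config()) {
  task_id <- match.arg(task_id, task_ids())
  ws <- workspace
  ctr <- ws$center
  res <- ws$path_resolution
  v_ref <- unname(ws$reference_speeds[[task_id]])
  if (!is.finite(v_ref) || v_ref <= 0)
    stop("reference speed must be positive", call. = FALSE)

  if (task_id %in% rom_tasks()) {
    r <- if (task_id == "small_rom") ws$small_rom_radius else ws$large_rom_radius
    # clockwise from 12 o'clock: angles pi/2, pi/4, 0, -pi/4, ...
    ang <- pi / 2 - (0:7) * pi / 4
    targets <- cbind(ctr[1] + r * cos(ang), ctr[2] + r * sin(ang))
    way <- matrix(ctr, nrow = 1)
    for (k in 1:8) way <- rbind(way, targets[k, ], ctr)
    path <- reference_path(way[, 1], way[, 2], closed = FALSE, resolution = res)
    spec <- list(task_id = task_id, targets = targets, waypoints = way,
                 reference_path = path, n_movements = 16L,
                 reference_speed = v_ref, guidance_gains = NULL, center = ctr)
  } else if (task_id %in% c("small_eight", "large_eight")) {
    a <- if (task_id == "small_eight") ws$eight_half_width_small else ws$eight_half_width_large
    if (a <= 0) stop("eight-shape half-width must be positive", call. = FALSE)
    pts <- lemniscate_points(ctr, a)
    path <- reference_path(pts[, 1], pts[, 2], closed = TRUE, resolution = res)
    spec <- list(task_id = task_id,
                 targets = matrix(ctr, nrow = 1),
                 waypoints = NULL,
                 reference_path = path, n_movements = 2L,  # laps of the eight
                 reference_speed = v_ref,
                 guidance_gains = ws$guidance_gains, center = ctr)
  } else {  # coins
    if (ws$coin_arc_radius <= 0) stop("coin arc radius must be positive", call. = FALSE)
    ang <- seq(5 * pi / 6, pi / 6, length.out = 5)  # upward arc, left to right
    coins <- cbind(ctr[1] + ws$coin_arc_radius * cos(ang),
                   ctr[2] + ws$coin_arc_radius * sin(ang))
    drops <- cbind(ctr[1] + (ws$coin_arc_radius + ws$coin_drop_offset) * cos(ang),
                   ctr[2] + (ws$coin_arc_radius + ws$coin_drop_offset) * sin(ang))
    way <- matrix(ctr, nrow = 1)
    for (k in 1:5) way <- rbind(way, coins[k, ], drops[k, ], ctr)
    path <- reference_path(way[, 1], way[, 2], closed = FALSE, resolution = res)
    spec <- list(task_id = task_id, targets = coins, waypoints = way,
                 drops = drops,
                 reference_path = path, n_movements = 5L,
                 reference_speed = v_ref,
                 guidance_gains = ws$guidance_gains, center = ctr)
  }
  structure(spec, class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task_spec> %s: %d target(s), %d movement(s), v_ref %.2f m/s, %s\n",
              x$task_id, nrow(x$targets), x$n_movements, x$reference_speed,
              if (is.null(x$guidance_gains)) "free mode" else "guided"))
  invisible(x)
}
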