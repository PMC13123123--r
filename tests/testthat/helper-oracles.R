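# Independent oracles used across test files. These deliberately avoid the
# package's own code paths (plain loops, explicit formulas).

# Exhaustive nearest-distance (m) of each sample to a polyline.
oracle_nearest_dist <- function(x, y, px, py) {
  vapply(seq_along(x), function(i) sqrt(min((px - x[i])^2 + (py - y[i])^2)), 0)
}

# Per-bin linear-scan covered area: for each of the 120 bins, scan all points.
oracle_area <- function(x, y, cx, cy) {
  dth <- 2 * pi / 120
  th <- atan2(y - cy, x - cx) %% (2 * pi)
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  total <- 0
  for (k in 1:120) {
    lo <- (k - 1) * dth
    hi <- k * dth
    inbin <- th >= lo & (th < hi | (k == 120 & th <= hi))
    rmax <- if (any(inbin)) max(r[inbin]) else 0
    total <- total + 0.5 * rmax^2 * dth
  }
  total
}

# Average ranks computed from first principles (sort + tie groups).
oracle_avg_ranks <- function(v) {
  o <- order(v)
  rk <- numeric(length(v))
  i <- 1
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
    rk[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  rk
}

# Pearson correlation from sum formulas.
oracle_pearson <- function(a, b) {
  n <- length(a)
  (n * sum(a * b) - sum(a) * sum(b)) /
    sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
}

# A small recording fixture on a given trajectory.
make_recording <- function(x, y, fx = 0 * x, fy = 0 * y, dt = 0.01,
                           task = "small_rom", limb = "LAS") {
  trial_recording("fix", limb, task, t = (seq_along(x) - 1) * dt,
                  x = x, y = y, fx = fx, fy = fy, sample_rate = 1 / dt)
}

small_eight_responses <- c("time_s", "work_total_j", "velocity_pct",
                           "accuracy_error_mm")
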