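#' Fuse odometry increments with optical position fixes
#'
#' Linear Kalman fusion on planar position: a constant-position process driven
#' by the odometry increments (process noise = per-step slip), corrected by
#' absolute optical fixes of the coded working surface whenever one is
#' available. Both axes share the same scalar variance (isotropic noise), so a
#' single Riccati recursion is tracked.
#'
#' @param odometry_increments m x 2 matrix of per-step planar displacement
#'   measurements (m).
#' @param optical_fixes m x 2 matrix of absolute position fixes aligned with
#'   the increment steps; rows of `NA` where no fix is available.
#' @param noise a [sensor_noise_spec()]; `odometry_slip_sd` is the per-step
#'   process noise SD, `optical_noise_sd` the measurement SD.
#' @param origin known starting position (the device zeroes its pose at task
#'   start), length-2 numeric.
#' @return a list with `estimate` (m x 2 fused positions after each step),
#'   `variance` (per-step posterior variance, m^2) and `unobservable`
#'   (logical: no fixes while process noise is positive).
#' @export
#' @examples
#' inc <- matrix(0.01, 5, 2)
#' opt <- matrix(NA_real_, 5, 2)
#' localize_fuse(inc, opt, sensor_noise_spec(0, 0, 25, 0))$estimate
localize_fuse <- function(odometry_increments, optical_fixes, noise,
                          origin = c(0, 0)) {
  inc <- as.matrix(odometry_increments)
  opt <- as.matrix(optical_fixes)
  if (ncol(inc) != 2L || !all(dim(inc) == dim(opt)))
    stop("increments and optical fixes must be time-aligned m x 2 matrices", call. = FALSE)
  m <- nrow(inc)
  Q <- noise$odometry_slip_sd^2
  R <- noise$optical_noise_sd^2
  cum <- apply(inc, 2, cumsum)
  if (m == 1L) cum <- matrix(cum, nrow = 1L)
  est <- matrix(NA_real_, m, 2)
  Pv <- numeric(m)
  fix_idx <- which(!is.na(opt[, 1]))
  unobservable <- length(fix_idx) == 0L && Q > 0
  if (unobservable)
    warning("no optical fixes while odometry slip is non-zero: position error unbounded",
            call. = FALSE)
  # sequential scalar recursion at fix times only; all between-fix estimates
  # are pure odometry prediction from the last posterior and are filled in
  # vectorized afterwards
  x1 <- origin[1]; x2 <- origin[2]
  P <- 0
  base <- 0L
  bc1 <- 0; bc2 <- 0
  nf <- length(fix_idx)
  fx1 <- numeric(nf); fx2 <- numeric(nf); fP <- numeric(nf)
  for (k in seq_len(nf)) {
    f <- fix_idx[k]
    xp1 <- x1 + cum[f, 1] - bc1
    xp2 <- x2 + cum[f, 2] - bc2
    Pp <- P + (f - base) * Q
    if (R == 0) {               # exact measurement
      x1 <- opt[f, 1]; x2 <- opt[f, 2]; P <- 0
    } else {
      K <- Pp / (Pp + R)
      x1 <- xp1 + K * (opt[f, 1] - xp1)
      x2 <- xp2 + K * (opt[f, 2] - xp2)
      P <- (1 - K) * Pp
    }
    fx1[k] <- x1; fx2[k] <- x2; fP[k] <- P
    base <- f
    bc1 <- cum[f, 1]; bc2 <- cum[f, 2]
  }
  steps <- seq_len(m)
  last <- findInterval(steps - 1L, fix_idx)          # index of last fix before step
  px1 <- c(origin[1], fx1)[last + 1L]
  px2 <- c(origin[2], fx2)[last + 1L]
  pc1 <- c(0, cum[fix_idx, 1])[last + 1L]
  pc2 <- c(0, cum[fix_idx, 2])[last + 1L]
  pP <- c(0, fP)[last + 1L]
  pbase <- c(0L, fix_idx)[last + 1L]
  est[, 1] <- px1 + cum[, 1] - pc1
  est[, 2] <- px2 + cum[, 2] - pc2
  Pv <- pP + (steps - pbase) * Q
  if (nf) {                                          # posterior at fix steps
    est[fix_idx, 1] <- fx1; est[fix_idx, 2] <- fx2
    Pv[fix_idx] <- fP
  }
  list(estimate = est, variance = Pv, unobservable = unobservable)
}
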