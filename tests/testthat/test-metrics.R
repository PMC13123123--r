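test_that("covered area: centre-only samples give zero, a circle gives pi R^2", {
  rec0 <- make_recording(rep(0, 10), rep(0, 10))
  expect_equal(compute_area(rec0, c(0, 0)), 0)
  th <- seq(0, 2 * pi, length.out = 1441)[-1441]
  circ <- make_recording(0.1 * cos(th), 0.1 * sin(th))
  expect_equal(compute_area(circ, c(0, 0)), pi * 0.01, tolerance = 5e-3)
})

test_that("covered area equals the per-bin linear-scan oracle on random clouds", {
  set.seed(11)
  x <- runif(1000); y <- runif(1000)
  rec <- make_recording(x, y)
  # exact up to floating-point summation order
  expect_equal(compute_area(rec, c(0.5, 0.5)), oracle_area(x, y, 0.5, 0.5),
               tolerance = 1e-13)
})

test_that("covered area is invariant to sample order and 3-degree rotations, and grows with samples", {
  set.seed(12)
  x <- runif(400, -0.1, 0.1); y <- runif(400, -0.1, 0.1)
  a0 <- compute_area(make_recording(x, y), c(0, 0))
  o <- sample(400)
  expect_equal(compute_area(make_recording(x[o], y[o]), c(0, 0)), a0)
  for (deg in c(3, 45, 90)) {
    th <- deg * pi / 180
    xr <- x * cos(th) - y * sin(th); yr <- x * sin(th) + y * cos(th)
    expect_equal(compute_area(make_recording(xr, yr), c(0, 0)), a0,
                 tolerance = 1e-12)
  }
  a_more <- compute_area(make_recording(c(x, 0.2), c(y, 0.2)), c(0, 0))
  expect_gte(a_more, a0)
})

test_that("work: constant aligned force and speed integrate exactly; zero force gives zero", {
  n <- 1001
  rec <- make_recording(x = 0.001 * (0:(n - 1)), y = rep(0, n),
                        fx = rep(1, n), fy = rep(0, n))
  w <- compute_work(rec)
  expect_equal(unname(w["work_total"]), 1.0, tolerance = 1e-9)   # 1 N x 0.1 m/s x 10 s
  expect_equal(unname(w["work_useful"]), 1.0, tolerance = 1e-9)
  rec0 <- make_recording(x = 0.001 * (0:(n - 1)), y = rep(0, n))
  expect_equal(unname(compute_work(rec0)), c(0, 0))
})

test_that("work at 100 Hz matches a 10 kHz dense integration oracle within 1%", {
  # analytic minimum-jerk reach with a sinusoidal force field
  D <- 0.2; Tm <- 2
  posf <- function(t) D * (10 * (t / Tm)^3 - 15 * (t / Tm)^4 + 6 * (t / Tm)^5)
  velf <- function(t) D / Tm * (30 * (t / Tm)^2 - 60 * (t / Tm)^3 + 30 * (t / Tm)^4)
  ff <- function(t) 2 + sin(2 * pi * t)
  t100 <- seq(0, Tm, by = 0.01)
  rec <- make_recording(posf(t100), 0 * t100, ff(t100), 0 * t100)
  w <- compute_work(rec)
  td <- seq(0, Tm, by = 1e-4)
  integrand <- abs(ff(td) * velf(td))
  oracle <- sum(diff(td) * (integrand[-1] + integrand[-length(td)]) / 2)
  expect_equal(unname(w["work_total"]), oracle, tolerance = 0.01)
})

test_that("work scales linearly with force gain and dominates useful work on constrained paths", {
  tk <- build_task("small_eight")
  rec <- simulate_trial(tk, impairment_profile(0.85, 0.004, 0.002, 5, 0.004, 1, 1.2),
                        sensor_noise_spec(), seed = 21)
  w1 <- compute_work(rec, tk$reference_path)
  expect_gte(w1["work_total"], abs(w1["work_useful"]))
  s <- rec$samples
  rec3 <- make_recording(s$x, s$y, 1.5 * s$fx, 1.5 * s$fy, task = "small_eight")
  w3 <- compute_work(rec3, tk$reference_path)
  expect_equal(unname(w3), 1.5 * unname(w1), tolerance = 1e-9)
})

test_that("velocity index: ratio of mean speed to reference, inverse in the reference", {
  n <- 501
  rec <- make_recording(0.001 * (0:(n - 1)), rep(0, n))
  expect_equal(compute_velocity(rec, 0.1), 100, tolerance = 1e-9)
  expect_equal(compute_velocity(rec, 0.2), 50, tolerance = 1e-9)
  still <- make_recording(rep(0.05, 10), rep(0, 10))
  expect_equal(compute_velocity(still, 0.1), 0)
  expect_error(compute_velocity(rec, 0), "> 0")
  # direct recomputation oracle on a simulated trial
  tk <- build_task("small_eight")
  sim <- simulate_trial(tk, impairment_profile(0.9, 0.003, 0.001, 5, 0.003, 0, 1.3),
                        sensor_noise_spec(), seed = 8)
  s <- sim$samples; m <- nrow(s)
  vx <- (s$x[3:m] - s$x[1:(m - 2)]) / (s$t[3:m] - s$t[1:(m - 2)])
  vy <- (s$y[3:m] - s$y[1:(m - 2)]) / (s$t[3:m] - s$t[1:(m - 2)])
  v1 <- c(sqrt((s$x[2] - s$x[1])^2 + (s$y[2] - s$y[1])^2) / (s$t[2] - s$t[1]))
  vM <- c(sqrt((s$x[m] - s$x[m - 1])^2 + (s$y[m] - s$y[m - 1])^2) / (s$t[m] - s$t[m - 1]))
  oracle <- 100 * mean(c(v1, sqrt(vx^2 + vy^2), vM)) / tk$reference_speed
  expect_equal(compute_velocity(sim, tk$reference_speed), oracle, tolerance = 1e-12)
})

test_that("accuracy error: zero on the path, constant offsets recovered, dense-search oracle", {
  p <- reference_path(c(-0.1, 0.1), c(0, 0))     # straight line y = 0
  xs <- seq(-0.09, 0.09, by = 0.005)   # on the 1 mm polyline grid
  on <- make_recording(xs, rep(0, length(xs)))
  expect_equal(compute_accuracy_error(on, p), 0, tolerance = 1e-9)
  off <- make_recording(xs, rep(0.005, length(xs)))
  expect_equal(compute_accuracy_error(off, p), 5, tolerance = 1e-6)
  # perturbed lemniscate vs exhaustive 0.1 mm search
  tk <- build_task("small_eight")
  rec <- simulate_trial(tk, impairment_profile(0.85, 0.005, 0.002, 5, 0.005, 1, 1.6),
                        sensor_noise_spec(), seed = 31)
  fine <- reference_path(tk$reference_path$x, tk$reference_path$y,
                         closed = TRUE, resolution = 1e-4)
  s <- rec$samples
  oracle <- 1000 * mean(oracle_nearest_dist(s$x, s$y, fine$x, fine$y))
  expect_lt(abs(compute_accuracy_error(rec, tk$reference_path) - oracle), 0.5)
})

test_that("accuracy error is invariant to time reparametrization; time is a translation-invariant difference", {
  tk <- build_task("small_eight")
  rec <- simulate_trial(tk, impairment_profile(0.9, 0.003, 0.001, 5, 0.003, 0, 1.3),
                        sensor_noise_spec(), seed = 9)
  s <- rec$samples
  warped <- trial_recording("w", "LAS", "small_eight", t = s$t^1.3 + 0.5,
                            x = s$x, y = s$y, fx = s$fx, fy = s$fy)
  expect_equal(compute_accuracy_error(warped, tk$reference_path),
               compute_accuracy_error(rec, tk$reference_path))
  t60 <- make_recording(seq(0, 0.6, length.out = 6001), rep(0, 6001))
  expect_equal(compute_time(t60), 60)
  shifted <- make_recording(seq(0, 0.6, length.out = 6001), rep(0, 6001))
  shifted$samples$t <- shifted$samples$t + 17
  expect_equal(compute_time(shifted), 60)
})

test_that("reports populate exactly the indices recorded for each task", {
  rom <- build_task("small_rom")
  r1 <- build_report(simulate_trial(rom, impairment_profile(), zero_noise(), seed = 2), rom)
  expect_false(is.na(r1$area_m2))
  expect_true(is.na(r1$accuracy_error_mm))
  coins <- build_task("coins")
  r2 <- build_report(simulate_trial(coins, impairment_profile(), zero_noise(), seed = 2), coins)
  expect_true(is.na(r2$area_m2))
  expect_false(is.na(r2$accuracy_error_mm))
  expect_equal(r2$time_min, r2$time_s / 60)
  expect_error(build_report(simulate_trial(rom, impairment_profile(), zero_noise(),
                                           seed = 2), coins),
               "task")
  # report CSV round-trip is lossless
  f <- withr::local_tempfile(fileext = ".csv")
  both <- rbind(r1, r2)
  write_reports_csv(both, f)
  back <- read_reports_csv(f)
  expect_equal(back$area_m2, both$area_m2)
  expect_equal(back$accuracy_error_mm, both$accuracy_error_mm)
  expect_equal(back$work_total_j, both$work_total_j)
})

test_that("metrics on a fixed recording are bit-stable across repeated evaluation", {
  tk <- build_task("coins")
  rec <- simulate_trial(tk, impairment_profile(0.9, 0.004, 0.001, 5, 0.003, 1, 1.4),
                        sensor_noise_spec(), seed = 55)
  a <- build_report(rec, tk)
  b <- build_report(rec, tk)
  expect_identical(a, b)
})
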