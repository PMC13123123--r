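test_that("guidance force is zero on the path, monotone in deviation, capped at 50 N", {
  tk <- build_task("small_eight")
  p <- tk$reference_path
  g <- tk$guidance_gains
  on_path <- guidance_force(c(p$x[10], p$y[10]), p, g)
  expect_equal(as.numeric(on_path), c(0, 0))
  # magnitude strictly increasing while below the cap
  d <- seq(0.002, 0.2, by = 0.002)
  pos <- cbind(p$x[1], p$y[1] + d)   # path point at the start, move away in y
  mag <- sqrt(rowSums(guidance_force(pos, p, g)^2))
  below <- mag < 50 - 1e-9
  expect_true(all(diff(mag[below]) > 0))
  # far away: exactly the 50 N cap
  far <- guidance_force(c(5, 5), p, g)
  expect_equal(sqrt(sum(far^2)), 50)
  expect_error(guidance_force(c(0, 0), list(), g), "reference_path")
})

test_that("an unimpaired noiseless trial tracks the eight within half a millimetre", {
  tk <- build_task("small_eight")
  rec <- simulate_trial(tk, impairment_profile(), zero_noise(), seed = 1)
  expect_lt(compute_accuracy_error(rec, tk$reference_path), 0.5)
  expect_equal(compute_velocity(rec, tk$reference_speed), 100, tolerance = 0.02)
})

test_that("recordings respect the device caps: speed <= 0.8 m/s, force <= 50 N", {
  heavy <- impairment_profile(speed_scale = 1, endpoint_jitter_sd = 0.02,
                              tremor_amplitude = 0.02, tremor_freq = 7,
                              path_wander_sd = 0.02, submovement_count = 2,
                              effort_inefficiency = 3)
  for (id in c("small_rom", "small_eight", "coins")) {
    rec <- simulate_trial(build_task(id), heavy, sensor_noise_spec(), seed = 7)
    s <- rec$samples
    speed <- sqrt(diff(s$x)^2 + diff(s$y)^2) / diff(s$t)
    expect_lte(max(speed), 0.8 + 1e-9)
    expect_lte(max(sqrt(s$fx^2 + s$fy^2)), 50 + 1e-9)
  }
})

test_that("the same seed reproduces a byte-identical recording", {
  tk <- build_task("coins")
  prof <- impairment_profile(0.85, 0.005, 0.002, 5.5, 0.003, 1, 1.5)
  a <- simulate_trial(tk, prof, sensor_noise_spec(), seed = 99)
  b <- simulate_trial(tk, prof, sensor_noise_spec(), seed = 99)
  expect_identical(a, b)
  c2 <- simulate_trial(tk, prof, sensor_noise_spec(), seed = 100)
  expect_false(identical(a$samples, c2$samples))
  expect_error(simulate_trial(tk, prof, sensor_noise_spec(), seed = -1), "seed")
})

test_that("completion time matches the generator's schedule within a sample period", {
  tk <- build_task("small_eight")
  rec <- simulate_trial(tk, impairment_profile(0.9, 0.003, 0.001, 5, 0.002, 1, 1.3),
                        sensor_noise_spec(), seed = 3)
  expect_lte(abs(compute_time(rec) - attr(rec, "scheduled_duration")), 0.01)
})

test_that("accuracy error and work are non-decreasing in each impairment parameter", {
  # averaged over 50 seeds, comparing a low and a high setting of one
  # parameter while all others stay fixed
  eight <- build_task("small_eight")
  rom <- build_task("small_rom")
  base <- list(speed_scale = 0.9, endpoint_jitter_sd = 0.003,
               tremor_amplitude = 0.001, tremor_freq = 5,
               path_wander_sd = 0.002, submovement_count = 0L,
               effort_inefficiency = 1.3)
  mean_over_seeds <- function(task, prof_args, fun) {
    prof <- do.call(impairment_profile, prof_args)
    mean(vapply(1:50, function(s)
      fun(simulate_trial(task, prof, zero_noise(), seed = s)), 0))
  }
  acc_fun <- function(rec) compute_accuracy_error(rec, eight$reference_path)
  work_fun <- function(rec) unname(compute_work(rec)["work_total"])

  for (par in c("tremor_amplitude", "path_wander_sd")) {
    lo <- base; hi <- base; hi[[par]] <- base[[par]] * 3
    expect_gt(mean_over_seeds(eight, hi, acc_fun),
              mean_over_seeds(eight, lo, acc_fun))
  }
  for (par in c("endpoint_jitter_sd", "effort_inefficiency", "submovement_count")) {
    lo <- base; hi <- base
    hi[[par]] <- if (par == "effort_inefficiency") 2.2 else
      if (par == "submovement_count") 2L else base[[par]] * 3
    expect_gt(mean_over_seeds(rom, hi, work_fun),
              mean_over_seeds(rom, lo, work_fun))
  }
})

test_that("trial logs round-trip through the raw CSV dialect", {
  tk <- build_task("small_eight")
  rec <- simulate_trial(tk, impairment_profile(0.9, 0.002, 0.001, 5, 0.002, 0, 1.2),
                        sensor_noise_spec(), seed = 5, participant_id = "P07",
                        limb = "MAS")
  f <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(rec, f)
  lines <- readLines(f, n = 5)
  expect_equal(lines[1], "# participant_id=P07")
  expect_equal(lines[4], "# sample_rate_hz=100")
  expect_equal(lines[5], "t_s,x_m,y_m,fx_n,fy_n")
  back <- read_trial_csv(f)
  expect_equal(back$participant_id, "P07")
  expect_equal(back$limb, "MAS")
  expect_lt(max(abs(back$samples$x - rec$samples$x)), 1e-7)
})
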