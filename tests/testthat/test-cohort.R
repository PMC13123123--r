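test_that("a default 28-child cohort reproduces the published marginal composition", {
  coh <- generate_cohort(28, cohort_config(tasks = "small_eight"), seed = 1)
  r <- coh$roster
  expect_equal(sum(r$macs == "I"), 16)
  expect_equal(sum(r$macs == "II"), 12)
  expect_equal(as.vector(table(r$hfcs)[as.character(4:8)]), c(5L, 8L, 3L, 8L, 4L))
  expect_equal(sum(r$hfcs_group == 1), 12)   # levels 7-8
  expect_equal(sum(r$hfcs_group == 2), 16)   # levels 4-6
  expect_equal(sum(r$sex == "female"), 8)
  expect_equal(sum(r$dominance == "right"), 13)
  expect_true(all(r$age >= 7 & r$age <= 18))
  expect_true(all(r$ma2_rom >= 7 & r$ma2_rom <= 27))
  expect_true(all(r$bbt_mas >= 4 & r$bbt_mas <= 56))
  # 2 limbs x 1 task per participant
  expect_length(coh$trials, 56)
  # grouping rule directly on the published level counts
  expect_equal(sum(hfcs_group(rep(4:8, c(5, 8, 3, 8, 4))) == 1), 12)
  expect_true(is.na(hfcs_group(3)))
})

test_that("cohorts are a pure function of (n, config, seed); trials are child-seeded", {
  cfg <- cohort_config(tasks = "coins")
  a <- generate_cohort(6, cfg, seed = 42)
  b <- generate_cohort(6, cfg, seed = 42)
  expect_identical(a$roster, b$roster)
  expect_identical(a$trials, b$trials)
  expect_identical(lapply(a$questionnaires$children, `[[`, "items"),
                   lapply(b$questionnaires$children, `[[`, "items"))
  c2 <- generate_cohort(6, cfg, seed = 43)
  expect_false(identical(a$roster, c2$roster))
  # a single trial regenerates in isolation from its child seed
  tk <- build_task("coins", cfg$workspace)
  rec <- simulate_trial(tk, a$profiles[["P03"]]$MAS, cfg$noise,
                        seed = child_seed(42, "P03", "MAS", "coins"),
                        participant_id = "P03", limb = "MAS")
  match_idx <- which(vapply(a$trials, function(tr)
    tr$participant_id == "P03" && tr$limb == "MAS", TRUE))
  expect_identical(a$trials[[match_idx]], rec)
})

test_that("the more affected side is strictly more impaired on every noise/effort axis", {
  coh <- generate_cohort(28, cohort_config(tasks = character(0), limbs = character(0)),
                         seed = 3)
  for (p in coh$profiles) {
    expect_gt(p$MAS$tremor_amplitude, p$LAS$tremor_amplitude)
    expect_gt(p$MAS$path_wander_sd, p$LAS$path_wander_sd)
    expect_gt(p$MAS$endpoint_jitter_sd, p$LAS$endpoint_jitter_sd)
    expect_gt(p$MAS$effort_inefficiency, p$LAS$effort_inefficiency)
    expect_gte(p$MAS$submovement_count, p$LAS$submovement_count)
  }
})

test_that("infeasible configurations are rejected", {
  expect_error(generate_cohort(28, cohort_config(macs_counts = c(I = 0, II = 0)),
                               seed = 1), "marginals")
  expect_error(cohort_config(rank_target_work = -0.99),
               "positive definite")
  expect_error(impairment_profile(speed_scale = 0), "speed_scale")
  expect_error(impairment_profile(effort_inefficiency = 0.5), "effort")
  expect_error(sensor_noise_spec(optical_rate = 200), "100 Hz")
})

test_that("marginals rescale proportionally for other cohort sizes", {
  coh <- generate_cohort(14, cohort_config(tasks = character(0), limbs = character(0)),
                         seed = 5)
  expect_equal(sum(coh$roster$macs == "I"), 8)     # 16/28 of 14
  expect_equal(nrow(coh$roster), 14)
})

test_that("with a rank target the realized Spearman between clinic and work lands within 0.1", {
  coh <- generate_cohort(500, cohort_config(tasks = "small_rom", limbs = "MAS",
                                            rank_target_work = -0.55), seed = 2)
  d <- merge(metrics_table(coh$trials), coh$roster, by = "participant_id")
  r <- cor(rank(d$bbt_mas), rank(d$work_total_j))
  expect_lt(abs(r - (-0.55)), 0.1)
})

test_that("a null configuration leaves the two limbs statistically indistinguishable", {
  # two-sample rank test on the small-eight accuracy error, alpha = 0.01,
  # across 50 seeds: non-significant in at least 45
  cfg <- cohort_config(tasks = "small_eight", effect_scale = 0)
  nonsig <- 0
  for (s in 1:50) {
    coh <- generate_cohort(12, cfg, seed = 1000 + s)
    m <- metrics_table(coh$trials)
    p <- wilcox.test(accuracy_error_mm ~ limb, data = m, exact = FALSE)$p.value
    nonsig <- nonsig + (p >= 0.01)
  }
  expect_gte(nonsig, 45)
})

test_that("questionnaire generation lands internal consistency in the plausible band", {
  coh <- generate_cohort(300, cohort_config(tasks = character(0), limbs = character(0)),
                         seed = 6)
  ch <- do.call(rbind, lapply(coh$questionnaires$children, `[[`, "items"))
  cl <- do.call(rbind, lapply(coh$questionnaires$clinicians, `[[`, "items"))
  expect_gt(cronbach_alpha(ch), 0.7)
  expect_lt(cronbach_alpha(ch), 0.9)
  expect_gt(cronbach_alpha(cl), 0.7)
  expect_lt(cronbach_alpha(cl), 0.9)
  expect_true(all(ch %in% 1:5))
  # children rate near the top of the smiley scale
  expect_gt(mean(ch), 3.8)
})

test_that("roster CSV round-trips", {
  coh <- generate_cohort(6, cohort_config(tasks = character(0), limbs = character(0)),
                         seed = 7)
  f <- withr::local_tempfile(fileext = ".csv")
  write_roster_csv(coh$roster, f)
  back <- read_roster_csv(f)
  expect_equal(back$participant_id, coh$roster$participant_id)
  expect_equal(back$hfcs, coh$roster$hfcs)
  expect_equal(back$macs, coh$roster$macs)
})
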