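#' Cohort-generation configuration
#'
#' Study conditions for the synthetic cohort: marginal composition of the
#' roster (classification levels, sex, dominance, age), the Gaussian-copula
#' latent-severity model linking clinical scores, per-limb impairment
#' profiles and questionnaire latents, the limb contrast (more affected side
#' strictly more impaired), and the sensing-noise model. Defaults emulate the
#' published cohort: 28 children, manual-ability levels I/II = 16/12,
#' hand-function levels 4-8 with counts 5/8/3/8/4 (groups 1/2 = 12/16),
#' female/male 8/20, right/left dominance 13/15, age 10.90 +/- 3.32 years in
#' 7-18.
#'
#' @param macs_counts named counts of manual-ability levels.
#' @param hfcs_counts named counts of hand-function levels (names "4".."8").
#' @param sex_counts,dominance_counts named marginal counts.
#' @param age_mean,age_sd,age_range truncated-normal age model (years).
#' @param rho_impair loading of the limb-impairment latent on the severity
#'   factor.
#' @param clinical_loadings named loadings of each clinical score on the
#'   severity factor.
#' @param rank_target_work optional target Spearman correlation between the
#'   more-affected-side Box-and-Block score and simulated work; when set, the
#'   Box-and-Block loading is solved from the Gaussian-copula identity
#'   `rho = 2 sin(pi * r_s / 6)`, with a fixed compensation for the known
#'   attenuation of the simulated measurement chain (instrument-range
#'   clipping ties, trial-level noise), so the realized rank correlation
#'   matches the target.
#' @param base baseline (less affected side, average severity) impairment
#'   parameters.
#' @param severity_scale exponent of the lognormal severity scaling of the
#'   impairment parameters.
#' @param limb_effect multiplicative/additive contrasts applied to the more
#'   affected side.
#' @param effect_scale global effect dial in `[0, 1]`: 1 = study conditions,
#'   0 = null configuration (no severity coupling, no limb contrast).
#' @param questionnaire Likert-response model: per-version item loadings on
#'   the respondent satisfaction latent (calibrated so internal consistency
#'   sits near 0.8), domain means, item SD, severity loading and the
#'   game-perception fraction.
#' @param tasks,limbs which tasks/limbs to simulate.
#' @param noise a [sensor_noise_spec()].
#' @param workspace a [workspace_config()].
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(macs_counts = c(I = 16, II = 12),
                          hfcs_counts = c(`4` = 5, `5` = 8, `6` = 3, `7` = 8, `8` = 4),
                          sex_counts = c(female = 8, male = 20),
                          dominance_counts = c(right = 13, left = 15),
                          age_mean = 10.90, age_sd = 3.32, age_range = c(7, 18),
                          rho_impair = 0.75,
                          clinical_loadings = c(hfcs = 0.85, macs = 0.75,
                                                ma2_rom = 0.70, ma2_accuracy = 0.65,
                                                ma2_dexterity = 0.70, ma2_fluency = 0.65,
                                                bbt_mas = 0.85, bbt_las = 0.30),
                          rank_target_work = NULL,
                          base = list(speed_scale = 0.90, endpoint_jitter_sd = 0.004,
                                      tremor_amplitude = 0.0008, path_wander_sd = 0.0025,
                                      effort_inefficiency_gain = 0.55,
                                      submovement_rate = 0.3),
                          severity_scale = 0.18,
                          limb_effect = list(tremor_mult = 1.6, wander_mult = 1.7,
                                             jitter_mult = 1.6, ineff_delta = 0.5,
                                             submove_delta = 1, speed_mult = 1.05),
                          effect_scale = 1,
                          questionnaire = list(item_loading = c(children = 0.52,
                                                                clinicians = 0.47),
                                               item_sd = 1.0,
                                               severity_loading = 0.15,
                                               children_means = c(usability = 4.55,
                                                                  acceptability = 4.40,
                                                                  motivation = 4.15),
                                               clinician_means = c(usability = 4.50,
                                                                   acceptability = 3.95),
                                               game_fraction = 17 / 28),
                          tasks = task_ids(), limbs = c("LAS", "MAS"),
                          noise = sensor_noise_spec(),
                          workspace = workspace_config()) {
  if (effect_scale < 0) stop("`effect_scale` must be >= 0", call. = FALSE)
  if (rho_impair <= 0 || rho_impair >= 1)
    stop("`rho_impair` must be in (0, 1)", call. = FALSE)
  if (!is.null(rank_target_work)) {
    # Gaussian-copula identity rho = 2 sin(pi r_s / 6), then compensation for
    # the attenuation of the simulated measurement chain (boundary ties after
    # clipping the clinical score to its instrument range, and trial-level
    # simulation noise in the work integral), estimated once from a large-n
    # calibration run of the full chain
    attenuation <- 1.06
    rho_needed <- attenuation * 2 * sin(pi * abs(rank_target_work) / 6) / rho_impair
    if (rho_needed >= 1)
      stop("correlation target infeasible: implied latent correlation matrix not positive definite",
           call. = FALSE)
    clinical_loadings["bbt_mas"] <- rho_needed
  }
  structure(list(macs_counts = macs_counts, hfcs_counts = hfcs_counts,
                 sex_counts = sex_counts, dominance_counts = dominance_counts,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 rho_impair = rho_impair, clinical_loadings = clinical_loadings,
                 rank_target_work = rank_target_work,
                 base = base, severity_scale = severity_scale,
                 limb_effect = limb_effect, effect_scale = effect_scale,
                 questionnaire = questionnaire,
                 tasks = tasks, limbs = limbs, noise = noise,
                 workspace = workspace),
            class = "cohort_config")
}

# Rescale a named count vector from its reference total to n participants,
# preserving the marginal proportions (largest-remainder rounding).
scale_counts <- function(counts, n) {
  tot <- sum(counts)
  if (tot == n) return(counts)
  raw <- counts / tot * n
  out <- floor(raw)
  rem <- n - sum(out)
  if (rem > 0) {
    ord <- order(raw - out, decreasing = TRUE)
    out[ord[seq_len(rem)]] <- out[ord[seq_len(rem)]] + 1
  }
  out
}

truncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# All copula latents (severity factor and per-latent innovations) share the
# same +/- 1.6 truncated standard normal law, so the correlation between any
# two latents is exactly the product of their severity loadings; TRUNC_SD
# restandardizes a latent to unit variance.
LATENT_BOUND <- 1.6
TRUNC_SD <- sqrt(1 - 2 * LATENT_BOUND * stats::dnorm(LATENT_BOUND) /
                   (2 * stats::pnorm(LATENT_BOUND) - 1))
latent_noise <- function(n) truncnorm(n, 0, 1, -LATENT_BOUND, LATENT_BOUND)

# Assign ordered categories by severity rank: the most severe participants
# receive the first (worst) category; the loading controls how imperfect a
# severity readout the category is.
assign_by_severity <- function(sev, loading, counts_worst_first, labels) {
  z <- loading * sev + sqrt(max(0, 1 - loading^2)) * latent_noise(length(sev))
  lab <- rep(labels, counts_worst_first)
  lab[rank(-z, ties.method = "first")]
}

# Clinical score as a monotone (negative) transform of the severity latent,
# rounded and clipped to the instrument range.
clinical_score <- function(sev, loading, mean, sd, range) {
  z <- (loading * sev + sqrt(max(0, 1 - loading^2)) * latent_noise(length(sev))) / TRUNC_SD
  round(clamp(mean - sd * z, range[1], range[2]))
}

# Map hand-function levels to the two severity groups (1 = levels 7-8,
# 2 = levels 4-6).
#' Hand-function severity group from raw levels
#'
#' Dichotomizes the 0-8 hand-function classification: group 1 for levels 7-8
#' (partial/complete spontaneous use), group 2 for levels 4-6 (active
#' assist); other levels are outside the study range and map to `NA`.
#'
#' @param hfcs integer vector of levels 0-8.
#' @return integer vector of groups (1, 2 or `NA`).
#' @export
#' @examples
#' table(hfcs_group(rep(4:8, c(5, 8, 3, 8, 4))))  # group 1 n = 12, group 2 n = 16
hfcs_group <- function(hfcs) {
  ifelse(hfcs %in% 7:8, 1L, ifelse(hfcs %in% 4:6, 2L, NA_integer_))
}

#' Generate a complete synthetic assessment cohort
#'
#' Draws a participant roster matching the configured marginal composition,
#' per-participant impairment profiles for both limbs through a Gaussian
#' copula on a shared latent severity factor (the more affected side strictly
#' more impaired under the default contrast), simulates every requested
#' limb x task trial through the full device model ([simulate_trial()]), and
#' generates 5-point Likert feasibility questionnaires from correlated
#' latents for both children and clinicians.
#'
#' Reproducible: the output is a pure function of `(n, config, seed)`; each
#' trial uses a child seed hashed from the participant, limb and task ids so
#' that any single trial can be regenerated in isolation.
#'
#' @param n number of participants.
#' @param config a [cohort_config()].
#' @param seed master seed (non-negative integer).
#' @return a list of class `cohort` with `roster` (data.frame), `profiles`
#'   (per participant, per limb [impairment_profile()]s), `trials` (list of
#'   [trial_recording()]s), `questionnaires` (`children` and `clinicians`
#'   lists of [questionnaire_response()]s), `config` and `seed`.
#' @export
#' @examples
#' coh <- generate_cohort(4, cohort_config(tasks = "small_eight"), seed = 7)
#' length(coh$trials)  # 4 participants x 2 limbs x 1 task
generate_cohort <- function(n = 28, config = cohort_config(), seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (n < 2) stop("need at least 2 participants", call. = FALSE)
  counts <- lapply(list(macs = config$macs_counts, hfcs = config$hfcs_counts,
                        sex = config$sex_counts, dominance = config$dominance_counts),
                   function(cc) {
                     if (sum(cc) <= 0) stop("infeasible marginals: counts sum to 0", call. = FALSE)
                     scale_counts(cc, n)
                   })
  if (any(vapply(counts, sum, 0) != n))
    stop("infeasible marginals: counts do not sum to n", call. = FALSE)

  es <- config$effect_scale
  loads <- config$clinical_loadings
  lim <- config$limb_effect
  mult <- function(m) 1 + es * (m - 1)
  ids <- sprintf("P%02d", seq_len(n))

  parts <- with_seed(seed, {
    # inclusion criteria bound the severity range (mild-to-moderate cohort),
    # so the severity factor and the impairment innovations are truncated
    sev <- truncnorm(n, 0, 1, -1.6, 1.6)

    # roster -----------------------------------------------------------------
    hfcs_levels <- sort(as.integer(names(counts$hfcs)))
    hfcs <- as.integer(assign_by_severity(
      sev, loads[["hfcs"]],
      counts$hfcs[as.character(hfcs_levels)], hfcs_levels))
    macs_levels <- names(counts$macs)[order(match(names(counts$macs), c("III", "II", "I")))]
    macs <- assign_by_severity(sev, loads[["macs"]],
                               counts$macs[macs_levels], macs_levels)
    roster <- data.frame(
      participant_id = ids,
      age = round(truncnorm(n, config$age_mean, config$age_sd,
                            config$age_range[1], config$age_range[2]), 2),
      sex = sample(rep(names(counts$sex), counts$sex)),
      dominance = sample(rep(names(counts$dominance), counts$dominance)),
      macs = macs, hfcs = hfcs, hfcs_group = hfcs_group(hfcs),
      ma2_rom = clinical_score(sev, loads[["ma2_rom"]], 19.54, 6.06, c(7, 27)),
      ma2_accuracy = clinical_score(sev, loads[["ma2_accuracy"]], 22.89, 3.34, c(13, 25)),
      ma2_dexterity = clinical_score(sev, loads[["ma2_dexterity"]], 11.11, 3.83, c(4, 16)),
      ma2_fluency = clinical_score(sev, loads[["ma2_fluency"]], 13.43, 4.26, c(6, 21)),
      bbt_las = clinical_score(sev, loads[["bbt_las"]], 50.96, 12.95, c(28, 75)),
      bbt_mas = clinical_score(sev, loads[["bbt_mas"]], 29.07, 15.21, c(4, 56)),
      stringsAsFactors = FALSE)

    # impairment profiles ----------------------------------------------------
    imp <- es * (config$rho_impair * sev +
                   sqrt(1 - config$rho_impair^2) * latent_noise(n))
    g <- exp(config$severity_scale * imp)
    # tremor intensity is less strongly graded by clinical severity than
    # effort and endpoint control; its severity scaling is compressed
    g_trem <- exp(0.7 * config$severity_scale * imp)
    b <- config$base
    tremor_freq <- stats::runif(n, 4, 7)
    # corrective-submovement propensity rises monotonically with severity;
    # the count is its rounded value (bounded), not an extra noise source
    submove_las <- pmin(as.integer(round(b$submovement_rate * g)), 2L)
    # severity-independent individual variation, drawn PER LIMB: the two arms
    # of a child differ in pace, effort and movement noise beyond what the
    # severity classification explains, so under a null configuration the two
    # limbs are exchangeable draws rather than copies
    idio_speed <- matrix(0.03 * latent_noise(2 * n), n, 2)
    idio_eff <- matrix(exp(0.05 * latent_noise(2 * n)), n, 2)
    idio_noise <- matrix(exp(0.05 * latent_noise(2 * n)), n, 2)
    limb_profile <- function(i, col, m_speed, m_jit, m_trem, m_wand,
                             sub_extra, eff_extra) {
      impairment_profile(
        speed_scale = clamp((b$speed_scale - 0.02 * imp[i] + idio_speed[i, col]) *
                              m_speed, 0.3, 1),
        # visual feedback and (on constrained tasks) resistive guidance bound
        # achievable deviation and effort, capping every severity scaling
        endpoint_jitter_sd = b$endpoint_jitter_sd *
          min(g[i] * idio_noise[i, col], 1.35) * m_jit,
        tremor_amplitude = b$tremor_amplitude *
          min(g_trem[i] * idio_noise[i, col], 1.35) * m_trem,
        tremor_freq = tremor_freq[i],
        path_wander_sd = b$path_wander_sd *
          min(g_trem[i] * idio_noise[i, col], 1.35) * m_wand,
        submovement_count = submove_las[i] + sub_extra,
        effort_inefficiency = 1 + b$effort_inefficiency_gain *
          min(g[i] * idio_eff[i, col], 1.35) + eff_extra)
    }
    profiles <- lapply(seq_len(n), function(i) {
      list(LAS = limb_profile(i, 1L, 1, 1, 1, 1, 0L, 0),
           MAS = limb_profile(i, 2L, mult(lim$speed_mult), mult(lim$jitter_mult),
                              mult(lim$tremor_mult), mult(lim$wander_mult),
                              as.integer(round(es * lim$submove_delta)),
                              es * lim$ineff_delta))
    })
    names(profiles) <- ids

    # questionnaires ---------------------------------------------------------
    qc <- config$questionnaire
    sat_child <- -es * qc$severity_loading * sev +
      sqrt(1 - (es * qc$severity_loading)^2) * stats::rnorm(n)
    sat_clin <- stats::rnorm(n)
    make_items <- function(sat_i, means, domains, lam) {
      mu <- means[domains]
      z <- lam * sat_i + sqrt(1 - lam^2) * stats::rnorm(length(domains))
      as.integer(clamp(round(mu + qc$item_sd * z), 1, 5))
    }
    lam_child <- if (length(qc$item_loading) > 1L) qc$item_loading[["children"]] else qc$item_loading
    lam_clin <- if (length(qc$item_loading) > 1L) qc$item_loading[["clinicians"]] else qc$item_loading
    dom_child <- questionnaire_domains("children")
    dom_clin <- questionnaire_domains("clinicians")
    children <- lapply(seq_len(n), function(i)
      questionnaire_response(ids[i], "children",
                             make_items(sat_child[i], qc$children_means, dom_child, lam_child)))
    clinicians <- lapply(seq_len(n), function(i)
      questionnaire_response(paste0("S", substring(ids[i], 2)), "clinicians",
                             make_items(sat_clin[i], qc$clinician_means, dom_clin, lam_clin)))
    n_game <- round(qc$game_fraction * n)
    game_rank <- rank(-(sat_child + 0.5 * stats::rnorm(n)), ties.method = "first")
    for (i in seq_len(n))
      children[[i]]$perceived_as <- if (game_rank[i] <= n_game) "game" else "therapy"

    list(roster = roster, profiles = profiles,
         children = children, clinicians = clinicians)
  })

  # trials (child-seeded, regenerable individually) --------------------------
  specs <- lapply(stats::setNames(config$tasks, config$tasks),
                  build_task, workspace = config$workspace)
  trials <- vector("list", n * length(config$limbs) * length(config$tasks))
  k <- 0L
  for (i in seq_len(n)) {
    for (limb in config$limbs) {
      prof <- parts$profiles[[i]][[limb]]
      for (task in config$tasks) {
        k <- k + 1L
        trials[[k]] <- simulate_trial(
          specs[[task]], prof, config$noise,
          seed = child_seed(seed, ids[i], limb, task),
          participant_id = ids[i], limb = limb)
      }
    }
  }

  structure(list(roster = parts$roster, profiles = parts$profiles,
                 trials = trials,
                 questionnaires = list(children = parts$children,
                                       clinicians = parts$clinicians),
                 config = config, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d trials (%s x %s)\n",
              nrow(x$roster), length(x$trials),
              paste(x$config$limbs, collapse = "/"),
              paste(x$config$tasks, collapse = ", ")))
  invisible(x)
}

#' Write / read the participant roster as CSV
#'
#' @param roster roster `data.frame` from [generate_cohort()].
#' @param path file path.
#' @return `write_roster_csv` returns `path` invisibly; `read_roster_csv`
#'   the roster `data.frame`.
#' @export
write_roster_csv <- function(roster, path) {
  utils::write.csv(roster, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_roster_csv
#' @export
read_roster_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character", macs = "character"))
}
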