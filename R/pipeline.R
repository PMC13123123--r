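#' Run configuration for the end-to-end pipeline
#'
#' @param seed master seed for the whole run.
#' @param n number of participants.
#' @param cohort a [cohort_config()], or a path to a YAML file whose keys
#'   override [cohort_config()] arguments.
#' @param output_dir directory for all run outputs (created if needed).
#' @param models which multivariate models to fit.
#' @param figures write descriptive figures (PDF)?
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed, n = 28, cohort = cohort_config(),
                       output_dir = tempfile("planarreach_run"),
                       models = c("model1_hfcs", "model2_macs"),
                       figures = TRUE) {
  if (is.character(cohort)) {
    if (!file.exists(cohort)) stop("cohort config file not found: ", cohort, call. = FALSE)
    args <- yaml::read_yaml(cohort)
    cohort <- do.call(cohort_config, args)
  }
  stopifnot(inherits(cohort, "cohort_config"))
  structure(list(seed = seed, n = n, cohort = cohort,
                 output_dir = output_dir, models = models, figures = figures),
            class = "run_config")
}

# Table-1 response set of one task (the indices the device records for it).
task_responses <- function(task) {
  if (task %in% rom_tasks())
    c("area_m2", "time_s", "work_total_j", "velocity_pct")
  else
    c("time_s", "work_total_j", "velocity_pct", "accuracy_error_mm")
}

# A-priori primary outcomes: area and work for the ROM tasks, accuracy error
# and velocity for the constrained tasks.
primary_outcomes <- function(task) {
  if (task %in% rom_tasks()) c("area_m2", "work_total_j")
  else c("accuracy_error_mm", "velocity_pct")
}

#' Fit both multivariate models for every task
#'
#' Joins the metric table with the roster and, per task, fits the requested
#' models ([manova_pillai()]) on the task's recorded indices with one row per
#' participant x limb.
#'
#' @param roster,metrics cohort roster and [metrics_table()] output.
#' @param models model ids (see [design_spec()]).
#' @return a list with `multivariate` and `univariate` stacked data.frames
#'   (columns `model`, `task` prepended).
#' @export
analyze_tasks <- function(roster, metrics, models = c("model1_hfcs", "model2_macs")) {
  merged <- merge(metrics, roster, by = "participant_id")
  mv <- list(); uv <- list()
  for (task in unique(merged$task)) {
    dat <- merged[merged$task == task, ]
    for (model in models) {
      des <- design_spec(model, responses = task_responses(task))
      res <- manova_pillai(dat, des)
      mv[[length(mv) + 1L]] <- cbind(model = model, task = task, res$multivariate)
      uv[[length(uv) + 1L]] <- cbind(model = model, task = task, res$univariate)
    }
  }
  list(multivariate = do.call(rbind, mv), univariate = do.call(rbind, uv))
}

stage_log <- function(log, stage, t0) {
  elapsed <- as.numeric(proc.time()["elapsed"]) - t0
  message(sprintf("[planarreach] %-10s done in %.1f s", stage, elapsed))
  rbind(log, data.frame(stage = stage, seconds = round(elapsed, 2)))
}

#' Run the full assessment pipeline
#'
#' Binds simulate -> metrics -> score -> analyze -> report into one
#' reproducible run: generates the cohort, computes every per-trial index
#' report, scores both questionnaire versions (with Cronbach's alpha),
#' screens the primary outcomes, fits both multivariate models per task,
#' builds the clinical-robotic correlation table, and writes all CSVs,
#' descriptive figures (mean +/- SD bar plots of the primary outcomes by
#' severity group and by limb; Likert boxplots) and a manifest with the
#' config hash, seed, per-stage timings and file checksums. Re-running with
#' the same config and seed reproduces identical data outputs.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (also written to `manifest.txt`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  log <- data.frame(stage = character(), seconds = numeric())
  t0 <- as.numeric(proc.time()["elapsed"])

  # simulate ------------------------------------------------------------
  coh <- generate_cohort(config$n, config$cohort, seed = config$seed)
  write_roster_csv(coh$roster, out("roster.csv"))
  write_questionnaire_csv(coh$questionnaires$children, out("questionnaire_children.csv"))
  write_questionnaire_csv(coh$questionnaires$clinicians, out("questionnaire_clinicians.csv"))
  log <- stage_log(log, "simulate", t0); t0 <- as.numeric(proc.time()["elapsed"])

  # metrics -------------------------------------------------------------
  metrics <- metrics_table(coh$trials, config$cohort$workspace)
  write_reports_csv(metrics, out("metrics.csv"))
  log <- stage_log(log, "metrics", t0); t0 <- as.numeric(proc.time()["elapsed"])

  # score ---------------------------------------------------------------
  qsum <- lapply(coh$questionnaires, summarize_questionnaires)
  alphas <- vapply(coh$questionnaires, function(resps)
    cronbach_alpha(do.call(rbind, lapply(resps, `[[`, "items"))), 0)
  dom <- do.call(rbind, lapply(names(qsum), function(v)
    cbind(version = v, qsum[[v]]$domains)))
  utils::write.csv(dom, out("questionnaire_summary.csv"), row.names = FALSE)
  log <- stage_log(log, "score", t0); t0 <- as.numeric(proc.time()["elapsed"])

  # analyze -------------------------------------------------------------
  prim <- do.call(rbind, lapply(unique(metrics$task), function(tk)
    data.frame(task = tk, outcome = primary_outcomes(tk))))
  screen_cols <- lapply(seq_len(nrow(prim)), function(i)
    metrics[metrics$task == prim$task[i], prim$outcome[i]])
  names(screen_cols) <- paste(prim$task, prim$outcome, sep = ".")
  screening <- screen_metrics(as.data.frame(screen_cols))
  utils::write.csv(screening$normality, out("screening.csv"), row.names = FALSE)
  stats_res <- analyze_tasks(coh$roster, metrics, config$models)
  utils::write.csv(stats_res$multivariate, out("manova_multivariate.csv"), row.names = FALSE)
  utils::write.csv(stats_res$univariate, out("manova_univariate.csv"), row.names = FALSE)
  corr <- correlation_table(coh$roster, metrics)
  utils::write.csv(corr, out("correlations.csv"), row.names = FALSE)
  log <- stage_log(log, "analyze", t0); t0 <- as.numeric(proc.time()["elapsed"])

  # report --------------------------------------------------------------
  if (isTRUE(config$figures)) {
    pipeline_figures(coh, metrics, config$output_dir)
  }
  cfg_yaml <- yaml::as.yaml(list(seed = config$seed, n = config$n,
                                 models = config$models))
  writeLines(cfg_yaml, out("config_echo.yaml"))
  log <- stage_log(log, "report", t0)

  files <- sort(setdiff(list.files(config$output_dir), "manifest.txt"))
  sums <- tools::md5sum(file.path(config$output_dir, files))
  manifest <- c(
    sprintf("config_hash: %s", substr(tools::md5sum(out("config_echo.yaml")), 1, 12)),
    sprintf("seed: %d", config$seed),
    sprintf("n_participants: %d", config$n),
    sprintf("package_version: %s", as.character(utils::packageVersion("planarreach"))),
    sprintf("cronbach_alpha_children: %.4f", alphas[["children"]]),
    sprintf("cronbach_alpha_clinicians: %.4f", alphas[["clinicians"]]),
    "stages:",
    sprintf("  %s: %.2f s", log$stage, log$seconds),
    "checksums:",
    sprintf("  %s  %s", unname(sums), files))
  writeLines(manifest, out("manifest.txt"))
  invisible(list(output_dir = config$output_dir, manifest = manifest,
                 cohort = coh, metrics = metrics, questionnaires = qsum,
                 alphas = alphas, screening = screening,
                 stats = stats_res, correlations = corr, timings = log))
}

# Descriptive figures: bar plots (mean +/- SD) of the a-priori primary
# outcomes by severity group and by limb, and Likert boxplots of the
# questionnaire domains. Bar plots are descriptive only (several indices are
# non-normal).
pipeline_figures <- function(coh, metrics, dir) {
  merged <- merge(metrics, coh$roster, by = "participant_id")
  prim <- do.call(rbind, lapply(unique(metrics$task), function(tk) {
    d <- merged[merged$task == tk, ]
    do.call(rbind, lapply(primary_outcomes(tk), function(oc)
      data.frame(task = tk, outcome = oc, limb = d$limb,
                 hfcs_group = factor(d$hfcs_group), value = d[[oc]])))
  }))
  agg <- function(by) {
    sp <- split(prim$value, list(prim$task, prim$outcome, prim[[by]]), drop = TRUE)
    info <- do.call(rbind, strsplit(names(sp), ".", fixed = TRUE))
    data.frame(task = info[, 1], outcome = info[, 2], group = info[, 3],
               mean = vapply(sp, mean, 0), sd = vapply(sp, stats::sd, 0))
  }
  bar <- function(df, lab) {
    ggplot2::ggplot(df, ggplot2::aes(x = task, y = mean, fill = group)) +
      ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sd, ymax = mean + sd),
                             position = ggplot2::position_dodge(0.9), width = 0.3) +
      ggplot2::facet_wrap(~outcome, scales = "free_y") +
      ggplot2::labs(x = NULL, y = "mean ± SD", fill = lab) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  }
  ggplot2::ggsave(file.path(dir, "primary_by_hfcs_group.pdf"),
                  bar(agg("hfcs_group"), "HFCS group"), width = 8, height = 5)
  ggplot2::ggsave(file.path(dir, "primary_by_limb.pdf"),
                  bar(agg("limb"), "limb"), width = 8, height = 5)

  lik <- do.call(rbind, lapply(names(coh$questionnaires), function(v) {
    resps <- coh$questionnaires[[v]]
    domains <- questionnaire_domains(v)
    do.call(rbind, lapply(resps, function(r)
      data.frame(version = v, domain = domains, rating = r$items)))
  }))
  p <- ggplot2::ggplot(lik, ggplot2::aes(x = domain, y = rating)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~version, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Likert rating (1-5)") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(dir, "likert_boxplots.pdf"), p, width = 7, height = 4)
  invisible(NULL)
}

#' Load a locally deposited study dataset
#'
#' Best-effort, mapping-driven loader for a local copy of the deposited
#' anonymized dataset: reads roster, per-trial metric and questionnaire CSV
#' tables from a directory and renames columns into the internal schemas. It
#' is never required by the synthetic pipeline; with a missing path the
#' loader warns and returns `NULL` so a run can proceed on synthetic data.
#'
#' @param path directory containing the dataset CSV files.
#' @param files named list of file names (`roster`, `metrics`,
#'   `questionnaires`); defaults match this package's own exports.
#' @param columns named character vector mapping external column names to
#'   internal ones (`c(external = "internal")`); unmapped columns must
#'   already carry internal names.
#' @return a list with `roster`, `metrics` and `questionnaires`
#'   (whichever files exist), or `NULL` with a warning if `path` is absent.
#' @export
load_deposited_dataset <- function(path,
                                   files = list(roster = "roster.csv",
                                                metrics = "metrics.csv",
                                                questionnaires = "questionnaire_children.csv"),
                                   columns = NULL) {
  if (is.null(path) || !dir.exists(path)) {
    warning("deposited dataset not found at '", path,
            "'; skipping (pipeline runs on synthetic data)", call. = FALSE)
    return(NULL)
  }
  remap <- function(df, required) {
    if (!is.null(columns)) {
      hit <- names(df) %in% names(columns)
      names(df)[hit] <- unname(columns[names(df)[hit]])
    }
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop("unmappable schema; unmatched internal columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    df
  }
  out <- list()
  if (file.exists(file.path(path, files$roster)))
    out$roster <- remap(utils::read.csv(file.path(path, files$roster),
                                        stringsAsFactors = FALSE),
                        c("participant_id", "macs", "hfcs"))
  if (file.exists(file.path(path, files$metrics)))
    out$metrics <- remap(utils::read.csv(file.path(path, files$metrics),
                                         stringsAsFactors = FALSE),
                         c("participant_id", "limb", "task"))
  if (file.exists(file.path(path, files$questionnaires)))
    out$questionnaires <- read_questionnaire_csv(file.path(path, files$questionnaires))
  out
}
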