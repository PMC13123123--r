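#' Screen a metric table for normality and outliers
#'
#' Per-column Shapiro-Wilk normality test and interquartile-range outlier
#' flags: values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` with
#' linear-interpolation quartiles (type 7). Constant columns have undefined
#' normality and are flagged as such rather than tested.
#'
#' @param table a `data.frame`; only numeric columns are screened.
#' @return a list with `normality` (data.frame: column, n, shapiro_w,
#'   shapiro_p, degenerate), `outliers` (logical matrix of flags) and
#'   `n_outliers` (named count per column).
#' @export
#' @examples
#' screen_metrics(data.frame(v = c(1, 2, 3, 4, 100)))$n_outliers
screen_metrics <- function(table) {
  num <- table[vapply(table, is.numeric, TRUE)]
  if (ncol(num) == 0L) stop("no numeric columns to screen", call. = FALSE)
  flags <- sapply(num, function(v) {
    v_ok <- v[is.finite(v)]
    q <- stats::quantile(v_ok, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    is.finite(v) & (v < q[1] - 1.5 * iqr | v > q[2] + 1.5 * iqr)
  })
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = nrow(num),
                                           dimnames = list(NULL, names(num)))
  normality <- do.call(rbind, lapply(names(num), function(nm) {
    v <- num[[nm]][is.finite(num[[nm]])]
    degenerate <- length(unique(v)) < 2L
    if (length(v) < 3L)
      stop(sprintf("column '%s': n < 3, normality test undefined", nm), call. = FALSE)
    if (degenerate) {
      data.frame(column = nm, n = length(v), shapiro_w = NA_real_,
                 shapiro_p = NA_real_, degenerate = TRUE)
    } else {
      sw <- stats::shapiro.test(v)
      data.frame(column = nm, n = length(v), shapiro_w = unname(sw$statistic),
                 shapiro_p = sw$p.value, degenerate = FALSE)
    }
  }))
  list(normality = normality, outliers = flags, n_outliers = colSums(flags))
}

#' Benjamini-Hochberg adjustment of a p-value family
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity, capped
#' at 1 (delegates to [stats::p.adjust()]).
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p-value vector", call. = FALSE)
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Specify one of the two multivariate models
#'
#' Each model pairs exactly one clinical factor (the 2-level more-affected-
#' hand function group for model 1, or the manual-ability level for model 2)
#' with limb condition, hand dominance, and age as a centered covariate; the
#' two clinical classifications are never entered together (conceptual
#' overlap and collinearity).
#'
#' @param model_id `"model1_hfcs"` or `"model2_macs"`.
#' @param responses character vector of response columns (the task's recorded
#'   indices).
#' @param clinical clinical factor column; defaults to `"hfcs_group"` for
#'   model 1 and `"macs"` for model 2 (set `"hfcs"` to use the raw levels).
#' @return a list of class `design_spec` with `predictors` ordered clinical,
#'   limb, dominance, age.
#' @export
design_spec <- function(model_id = c("model1_hfcs", "model2_macs"),
                        responses, clinical = NULL) {
  model_id <- match.arg(model_id)
  if (is.null(clinical))
    clinical <- if (model_id == "model1_hfcs") "hfcs_group" else "macs"
  if (all(c("hfcs_group", "macs") %in% clinical))
    stop("exactly one clinical factor per model", call. = FALSE)
  structure(list(model_id = model_id, responses = responses,
                 clinical = clinical,
                 predictors = c(clinical, "limb", "dominance", "age")),
            class = "design_spec")
}

#' MANOVA with Pillai's Trace and FDR-adjusted univariate follow-ups
#'
#' Fits a multivariate linear model of the response columns on the design's
#' predictors (one row per participant x limb) and tests each term with
#' Pillai's Trace `V = tr(H (H + E)^-1)`, where the hypothesis cross-product
#' matrix `H` is the extra residual cross-product of the model without the
#' term (marginal test) and `E` is the full-model residual cross-product.
#' The F approximation, numerator and denominator degrees of freedom follow
#' the standard Pillai formulation; the multivariate partial eta squared is
#' `V / s` with `s = min(p, q)`. Univariate follow-ups per response use the
#' same full/reduced residual sums of squares, with Benjamini-Hochberg
#' adjustment across the responses within each term and univariate partial
#' eta squared `SS_term / (SS_term + SS_res)`.
#'
#' Numeric predictors (age) are centered before fitting; factors use
#' treatment coding with reference levels LAS (limb), group 1, MACS I and
#' right (dominance) where those levels are present.
#'
#' @param table trial-level `data.frame`, one row per participant x limb,
#'   containing the response and predictor columns (complete cases required).
#' @param design a [design_spec()].
#' @return a list of class `manova_result`: `multivariate` (data.frame: term,
#'   df, pillai, F, df1, df2, p, eta_p_sq) and `univariate` (data.frame:
#'   term, response, F, df1, df2, p, p_adj, eta_p_sq).
#' @export
manova_pillai <- function(table, design) {
  stopifnot(inherits(design, "design_spec"))
  resp <- design$responses
  preds <- design$predictors
  miss <- setdiff(c(resp, preds), names(table))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  dat <- table[c(resp, preds)]
  if (anyNA(dat)) stop("complete cases required", call. = FALSE)
  if (length(resp) < 1L) stop("at least one response is required", call. = FALSE)

  ref_pref <- list(limb = "LAS", hfcs_group = "1", macs = "I", dominance = "right")
  for (p in preds) {
    v <- dat[[p]]
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      f <- factor(v)
      pref <- ref_pref[[p]]
      if (!is.null(pref) && pref %in% levels(f)) f <- stats::relevel(f, pref)
      dat[[p]] <- f
    } else {
      dat[[p]] <- v - mean(v)  # centered covariate
    }
  }
  Y <- as.matrix(dat[resp])
  X <- stats::model.matrix(stats::reformulate(preds), dat)
  asg <- attr(X, "assign")
  n <- nrow(X)
  qr_full <- qr(X)
  if (qr_full$rank < ncol(X)) {
    aliased <- colnames(X)[qr_full$pivot[(qr_full$rank + 1L):ncol(X)]]
    stop("rank-deficient design; aliased: ", paste(aliased, collapse = ", "),
         call. = FALSE)
  }
  res_full <- qr.resid(qr_full, Y)
  E <- crossprod(res_full)
  dfe <- n - qr_full$rank
  p_resp <- length(resp)
  if (dfe < p_resp) stop("singular error matrix: too few error df", call. = FALSE)

  mv <- list(); uv <- list()
  for (ti in seq_along(preds)) {
    keep <- asg != ti
    qr_red <- qr(X[, keep, drop = FALSE])
    res_red <- qr.resid(qr_red, Y)
    H <- crossprod(res_red) - E
    q <- qr_full$rank - qr_red$rank
    HE <- H + E
    V <- sum(diag(solve(HE, H)))
    s <- min(p_resp, q)
    mm <- (abs(p_resp - q) - 1) / 2
    nn <- (dfe - p_resp - 1) / 2
    df1 <- s * (2 * mm + s + 1)
    df2 <- s * (2 * nn + s + 1)
    Fstat <- ((2 * nn + s + 1) / (2 * mm + s + 1)) * (V / s) / (1 - V / s)
    mv[[ti]] <- data.frame(term = preds[ti], df = q, pillai = V, F = Fstat,
                           df1 = df1, df2 = df2,
                           p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
                           eta_p_sq = V / s)
    ssh <- diag(H); sse <- diag(E)
    Fu <- (ssh / q) / (sse / dfe)
    pu <- stats::pf(Fu, q, dfe, lower.tail = FALSE)
    uv[[ti]] <- data.frame(term = preds[ti], response = resp, F = Fu,
                           df1 = q, df2 = dfe, p = pu,
                           p_adj = bh_adjust(pu),
                           eta_p_sq = ssh / (ssh + sse),
                           row.names = NULL)
  }
  structure(list(model_id = design$model_id,
                 multivariate = do.call(rbind, mv),
                 univariate = do.call(rbind, uv),
                 n = n, dfe = dfe),
            class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf("<manova_result> %s (n = %d observations)\n", x$model_id, x$n))
  print(x$multivariate, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Spearman correlation with a strength category
#'
#' Rank correlation on average ranks (ties allowed), a t-approximation
#' p-value, and the conventional strength category of the absolute
#' coefficient: slight (< 0.20), low (0.20-0.40), moderate (0.40-0.70), high
#' (0.70-0.90) and very strong (> 0.90); the bands are half-open on the
#' right except high, which includes 0.90.
#'
#' @param x,y numeric vectors (n >= 4, non-constant).
#' @param clinical_measure,task,metric optional labels carried into the
#'   result.
#' @return a one-row `data.frame`: clinical_measure, task, metric,
#'   spearman_r, p, category, stars (`*` p < .05, `**` p < .01).
#' @export
#' @examples
#' spearman_with_category(1:10, (1:10)^2)  # r = 1, "very strong"
spearman_with_category <- function(x, y, clinical_measure = NA_character_,
                                   task = NA_character_, metric = NA_character_) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  r <- stats::cor(rank(x, ties.method = "average"),
                  rank(y, ties.method = "average"))
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  data.frame(clinical_measure = clinical_measure, task = task, metric = metric,
             spearman_r = r, p = p,
             category = spearman_category(r),
             stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
             stringsAsFactors = FALSE)
}

spearman_category <- function(r) {
  a <- abs(r)
  if (a > 0.90) "very strong"
  else if (a >= 0.70) "high"
  else if (a >= 0.40) "moderate"
  else if (a >= 0.20) "low"
  else "slight"
}

#' Correlation table between clinical measures and robotic indices
#'
#' Spearman correlations (with categories and significance stars) between
#' each clinical classification/score of the roster and each task x index
#' cell of the metric table, using the more-affected-side trial of each
#' participant (the clinical measures describe the more affected limb).
#'
#' @param roster participant `data.frame` from [generate_cohort()] (columns
#'   `hfcs`, `hfcs_group`, `macs`, `ma2_*`, `bbt_mas`, ...).
#' @param metrics metric table from [metrics_table()].
#' @param clinical character vector of roster columns to correlate.
#' @param limb which limb's trials to use (default `"MAS"`).
#' @return a long `data.frame` of [spearman_with_category()] rows.
#' @export
correlation_table <- function(roster, metrics,
                              clinical = c("hfcs", "hfcs_group", "macs",
                                           "ma2_rom", "ma2_accuracy",
                                           "ma2_dexterity", "ma2_fluency",
                                           "bbt_mas"),
                              limb = "MAS") {
  m <- metrics[metrics$limb == limb, ]
  idx_cols <- c("area_m2", "time_s", "work_total_j", "velocity_pct",
                "accuracy_error_mm")
  out <- list()
  for (cl in clinical) {
    cvals <- roster[[cl]]
    if (is.character(cvals) || is.factor(cvals)) cvals <- as.integer(factor(cvals))
    names(cvals) <- roster$participant_id
    for (tk in unique(m$task)) {
      mt <- m[m$task == tk, ]
      for (ix in idx_cols) {
        v <- mt[[ix]]
        if (all(is.na(v))) next
        out[[length(out) + 1L]] <-
          spearman_with_category(cvals[mt$participant_id], v,
                                 clinical_measure = cl, task = tk, metric = ix)
      }
    }
  }
  do.call(rbind, out)
}
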