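# Domain layout of the two feasibility-questionnaire versions. Items are
# positional (their text is not part of the scoring): children answer 8
# usability + 8 acceptability + 2 motivation items, clinicians 8 + 8, all on a
# 1-5 Likert scale (1 most negative, 5 most positive).
questionnaire_domains <- function(version) {
  version <- match.arg(version, c("children", "clinicians"))
  if (version == "children")
    rep(c("usability", "acceptability", "motivation"), c(8L, 8L, 2L))
  else
    rep(c("usability", "acceptability"), c(8L, 8L))
}

questionnaire_item_names <- function(version) {
  d <- questionnaire_domains(version)
  prefix <- c(usability = "u", acceptability = "a", motivation = "m")[d]
  paste0(prefix, stats::ave(seq_along(d), d, FUN = seq_along))
}

#' Feasibility-questionnaire response
#'
#' @param respondent_id character id.
#' @param version `"children"` (18 items: 8 usability, 8 acceptability,
#'   2 motivation) or `"clinicians"` (16 items: 8 + 8).
#' @param items ordered integer responses, each in 1..5.
#' @param perceived_as `"game"` or `"therapy"` (children only).
#' @return a list of class `questionnaire_response`.
#' @export
questionnaire_response <- function(respondent_id, version, items,
                                   perceived_as = NA_character_) {
  version <- match.arg(version, c("children", "clinicians"))
  domains <- questionnaire_domains(version)
  items <- as.integer(items)
  if (length(items) != length(domains))
    stop(sprintf("'%s' questionnaire has %d items, got %d",
                 version, length(domains), length(items)), call. = FALSE)
  if (anyNA(items) || any(items < 1L | items > 5L))
    stop("all item responses must be integers in 1..5", call. = FALSE)
  if (!is.na(perceived_as))
    perceived_as <- match.arg(perceived_as, c("game", "therapy"))
  structure(list(respondent_id = as.character(respondent_id),
                 version = version, items = items,
                 perceived_as = perceived_as),
            class = "questionnaire_response")
}

#' Score a feasibility questionnaire
#'
#' Per-domain raw sums with their possible ranges and percentage of the
#' maximum, plus the total score: usability and acceptability range 8-40
#' each, motivation (children only) 2-10; the total maximum is 90 for
#' children and 80 for clinicians.
#'
#' @param resp a [questionnaire_response()].
#' @return a `data.frame` with columns `domain, raw, min_possible,
#'   max_possible, percentage` (percentages rounded to 2 decimals); the last
#'   row is the total.
#' @export
#' @examples
#' r <- questionnaire_response("c1", "clinicians", rep(5, 16))
#' score_questionnaire(r)  # total 80, 100%
score_questionnaire <- function(resp) {
  stopifnot(inherits(resp, "questionnaire_response"))
  domains <- questionnaire_domains(resp$version)
  raw <- tapply(resp$items, domains, sum)
  k <- tapply(domains, domains, length)
  ord <- unique(domains)
  out <- data.frame(domain = c(ord, "total"),
                    raw = c(as.numeric(raw[ord]), sum(resp$items)),
                    min_possible = c(as.numeric(k[ord]), length(domains)),
                    max_possible = c(5 * as.numeric(k[ord]), 5 * length(domains)),
                    stringsAsFactors = FALSE)
  out$percentage <- round(100 * out$raw / out$max_possible, 2)
  out
}

#' Summarize feasibility questionnaires over a cohort
#'
#' Domain totals as mean +/- SD (sample SD, n - 1 denominator), observed
#' range, and the cohort percentage of the maximum (cohort mean over domain
#' maximum); per-item Likert means per domain; and the game/therapy
#' perception proportions (1 decimal) for the children's version.
#'
#' @param responses list of [questionnaire_response()]s of a single version.
#' @return a list with `domains` (data.frame: domain, mean, sd, min, max,
#'   percentage), `likert` (data.frame: domain, mean, sd of item-level
#'   ratings), `perception` (data.frame: perceived_as, n, percentage; `NULL`
#'   for clinicians), `n`, and `version`. With a single respondent the SD is
#'   undefined and flagged as `NA`.
#' @export
summarize_questionnaires <- function(responses) {
  if (length(responses) == 0L) stop("empty cohort", call. = FALSE)
  stopifnot(all(vapply(responses, inherits, TRUE, "questionnaire_response")))
  version <- unique(vapply(responses, `[[`, "", "version"))
  if (length(version) != 1L)
    stop("all responses must be of the same questionnaire version", call. = FALSE)
  domains <- questionnaire_domains(version)
  mat <- do.call(rbind, lapply(responses, `[[`, "items"))
  scores <- lapply(responses, score_questionnaire)
  per_dom <- do.call(rbind, lapply(scores, function(s) s$raw))
  colnames(per_dom) <- scores[[1]]$domain
  n <- length(responses)
  dom_tab <- data.frame(
    domain = colnames(per_dom),
    mean = colMeans(per_dom),
    sd = if (n > 1L) apply(per_dom, 2, stats::sd) else NA_real_,
    min = apply(per_dom, 2, min),
    max = apply(per_dom, 2, max),
    max_possible = scores[[1]]$max_possible,
    stringsAsFactors = FALSE, row.names = NULL)
  dom_tab$percentage <- round(100 * dom_tab$mean / dom_tab$max_possible, 2)
  likert <- do.call(rbind, lapply(unique(domains), function(d) {
    v <- as.numeric(mat[, domains == d])
    data.frame(domain = d, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
  }))
  perception <- NULL
  if (version == "children") {
    pa <- vapply(responses, `[[`, "", "perceived_as")
    pa <- pa[!is.na(pa)]
    if (length(pa)) {
      cnt <- table(factor(pa, levels = c("game", "therapy")))
      perception <- data.frame(perceived_as = names(cnt),
                               n = as.integer(cnt),
                               percentage = round(100 * as.integer(cnt) / length(pa), 1),
                               stringsAsFactors = FALSE)
    }
  }
  list(version = version, n = n, domains = dom_tab, likert = likert,
       perception = perception)
}

#' Percentage of the maximum domain score
#'
#' Renders a raw (or cohort-mean) domain score as the percentage of the
#' domain's maximum possible score, the form in which feasibility results are
#' reported (rounded to 2 decimals).
#'
#' @param raw raw or mean domain score.
#' @param domain `"usability"`, `"acceptability"`, `"motivation"` or
#'   `"total"`.
#' @param version `"children"` or `"clinicians"`.
#' @return percentage of the maximum (numeric).
#' @export
#' @examples
#' domain_percentage(34.79, "usability", "children")  # 86.97
domain_percentage <- function(raw, domain, version) {
  version <- match.arg(version, c("children", "clinicians"))
  domains <- questionnaire_domains(version)
  domain <- match.arg(domain, c(unique(domains), "total"))
  k <- if (domain == "total") length(domains) else sum(domains == domain)
  round(100 * raw / (5 * k), 2)
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient of a multi-item scale:
#' `alpha = k/(k - 1) * (1 - sum(item variances) / variance(total score))`
#' with sample (n - 1) variances.
#'
#' @param item_matrix numeric matrix, respondents in rows, items in columns
#'   (at least 2 of each).
#' @return Cronbach's alpha (dimensionless).
#' @export
#' @examples
#' set.seed(1)
#' z <- rnorm(50)
#' m <- sapply(1:4, function(i) z + rnorm(50, sd = 0.8))
#' cronbach_alpha(m)
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 respondents and 2 items", call. = FALSE)
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) stop("zero total-score variance", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Write / read questionnaire responses as CSV
#'
#' One row per respondent with columns `respondent_id`, `version`,
#' `perceived_as` and the item columns `u1..u8,a1..a8[,m1,m2]`.
#'
#' @param responses list of [questionnaire_response()]s of a single version.
#' @param path file path.
#' @return `write_questionnaire_csv` returns `path` invisibly;
#'   `read_questionnaire_csv` returns a list of responses.
#' @export
write_questionnaire_csv <- function(responses, path) {
  version <- unique(vapply(responses, `[[`, "", "version"))
  stopifnot(length(version) == 1L)
  mat <- do.call(rbind, lapply(responses, `[[`, "items"))
  colnames(mat) <- questionnaire_item_names(version)
  df <- data.frame(respondent_id = vapply(responses, `[[`, "", "respondent_id"),
                   version = version,
                   perceived_as = vapply(responses, `[[`, "", "perceived_as"),
                   mat, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_questionnaire_csv
#' @export
read_questionnaire_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(respondent_id = "character"))
  lapply(seq_len(nrow(df)), function(i) {
    version <- df$version[i]
    items <- as.integer(df[i, questionnaire_item_names(version)])
    pa <- df$perceived_as[i]
    questionnaire_response(df$respondent_id[i], version, items,
                           if (is.null(pa) || is.na(pa) || pa == "") NA_character_ else pa)
  })
}
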