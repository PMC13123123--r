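# Gauss hypergeometric 2F1(1/2, 1/2; c; x) by its power series; x in [0, 1),
# c > 1. Converges quickly for the arguments arising in the correlation
# density (x <= (1 + |rho|)/2 < 1).
hyp2f1_half <- function(c0, x) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    term <- 1; acc <- 1; k <- 0
    while (abs(term) > 1e-15 * abs(acc) && k < 500) {
      term <- term * (0.5 + k)^2 / ((c0 + k) * (k + 1)) * x[i]
      acc <- acc + term
      k <- k + 1
    }
    out[i] <- acc
  }
  out
}

#' Exact density of the sample correlation coefficient
#'
#' Density of Pearson's r from a bivariate normal sample of size `n` with
#' population correlation `rho` (Hotelling's hypergeometric form).
#'
#' @param r evaluation points in (-1, 1).
#' @param n sample size (>= 4).
#' @param rho population correlation, |rho| < 1.
#' @return density values.
#' @export
dcorr <- function(r, n, rho) {
  stopifnot(n >= 4, abs(rho) < 1)
  lc <- log(n - 2) + lgamma(n - 1) + ((n - 1) / 2) * log1p(-rho^2) -
    0.5 * log(2 * pi) - lgamma(n - 0.5)
  ld <- ((n - 4) / 2) * log1p(-r^2) - (n - 1.5) * log1p(-rho * r)
  exp(lc + ld) * hyp2f1_half(n - 0.5, (1 + rho * r) / 2)
}

#' Power of the two-sided test of zero correlation
#'
#' For a bivariate normal sample of size `n` with true correlation `rho`,
#' power of the two-tailed level-`alpha` t-test of H0: rho = 0. The critical
#' sample correlation comes from the t distribution at `n`; in `"exact"` mode
#' the rejection probability integrates the exact distribution of the sample
#' correlation under the alternative, in `"fisher"` mode it uses the
#' Fisher-z normal approximation.
#'
#' @param n sample size (>= 4).
#' @param rho true correlation, |rho| < 1.
#' @param alpha two-sided significance level.
#' @param method `"exact"` or `"fisher"`.
#' @return power in (0, 1).
#' @export
power_correlation <- function(n, rho, alpha = 0.05,
                              method = c("exact", "fisher")) {
  method <- match.arg(method)
  stopifnot(n >= 4, abs(rho) < 1, alpha > 0, alpha < 1)
  if (method == "exact") {
    tc <- stats::qt(1 - alpha / 2, df = n - 2)
    rc <- tc / sqrt(tc^2 + n - 2)
    up <- stats::integrate(dcorr, rc, 1, n = n, rho = rho,
                           rel.tol = 1e-10, abs.tol = 1e-12)$value
    lo <- stats::integrate(dcorr, -1, -rc, n = n, rho = rho,
                           rel.tol = 1e-10, abs.tol = 1e-12)$value
    up + lo
  } else {
    # canonical Fisher-z normal approximation in z space
    se <- 1 / sqrt(n - 3)
    zr <- atanh(rho)
    za <- stats::qnorm(1 - alpha / 2)
    stats::pnorm(abs(zr) / se - za) + stats::pnorm(-abs(zr) / se - za)
  }
}

#' Minimum sample size to detect a correlation
#'
#' Smallest `n` at which the two-sided level-`alpha` test of zero correlation
#' reaches the desired power under a bivariate normal model with true
#' correlation `rho`. The default `"exact"` mode evaluates the exact
#' distribution of the sample correlation; the `"fisher"` mode uses the
#' closed-form Fisher-z approximation
#' `ceil(((z_{alpha/2} + z_beta) / atanh(rho))^2 + 3)` (computed by the same
#' upward search on the approximate power, which agrees with the closed
#' form).
#'
#' @param rho true correlation, 0 < |rho| < 1.
#' @param alpha two-sided significance level.
#' @param power desired power in (0, 1).
#' @param method `"exact"` or `"fisher"`.
#' @param n_max search bound.
#' @return minimum sample size (integer).
#' @export
#' @examples
#' required_n_correlation(0.53)                       # 25
#' required_n_correlation(0.53, method = "fisher")    # 26
required_n_correlation <- function(rho, alpha = 0.05, power = 0.80,
                                   method = c("exact", "fisher"),
                                   n_max = 10000L) {
  method <- match.arg(method)
  if (abs(rho) >= 1 || rho == 0) stop("need 0 < |rho| < 1", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  for (n in 4:n_max) {
    if (power_correlation(n, rho, alpha, method) >= power) return(n)
  }
  stop("no n <= n_max reaches the desired power", call. = FALSE)
}

#' Inflate a sample size for expected dropout
#'
#' `ceil(n / (1 - rate))`, the usual enrolment target so that `n`
#' participants remain after a dropout fraction `rate`.
#'
#' @param n required analyzable sample size.
#' @param rate anticipated dropout proportion in `[0, 1)`.
#' @return target enrolment (integer).
#' @export
#' @examples
#' inflate_for_dropout(25, 0.10)  # 28
inflate_for_dropout <- function(n, rate) {
  stopifnot_scalar(n, "n", positive = TRUE)
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1)
    stop("`rate` must be in [0, 1)", call. = FALSE)
  as.integer(ceiling(n / (1 - rate)))
}

#' Approximate a-priori power for a Pillai-trace global effect
#'
#' Noncentral-F approximation of the power of the Pillai multivariate test
#' for a global effect of size `f2` (the multivariate f-squared, V/(1-V))
#' with `n_groups` groups and `n_responses` response variables at total
#' sample size `n`. Provided for completeness of the power module; its
#' result depends on design constants (group and response counts) that any
#' given study must supply.
#'
#' @param n total sample size.
#' @param f2 multivariate effect size f^2(V).
#' @param n_groups number of groups of the tested factor.
#' @param n_responses number of response variables.
#' @param alpha significance level.
#' @return approximate power.
#' @export
power_manova_pillai <- function(n, f2, n_groups, n_responses, alpha = 0.05) {
  stopifnot(n > n_groups, f2 > 0, n_groups >= 2, n_responses >= 1)
  q <- n_groups - 1
  p <- n_responses
  s <- min(p, q)
  mm <- (abs(p - q) - 1) / 2
  nn <- ((n - n_groups) - p - 1) / 2
  df1 <- s * (2 * mm + s + 1)
  df2 <- s * (2 * nn + s + 1)
  lambda <- f2 * (df2 + df1 + 1)
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}
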