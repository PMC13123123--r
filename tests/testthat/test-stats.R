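test_that("IQR screening flags the hand-worked outlier and handles degenerate columns", {
  sc <- screen_metrics(data.frame(v = c(1, 2, 3, 4, 100)))
  # type-7 quartiles: Q1 = 2, Q3 = 4, upper fence 4 + 1.5*2 = 7 -> only 100
  expect_equal(unname(sc$n_outliers), 1)
  expect_equal(which(sc$outliers[, "v"]), 5L)
  const <- screen_metrics(data.frame(a = c(1, 2, 3, 4, 100), b = rep(2, 5)))
  expect_equal(unname(const$n_outliers["b"]), 0)
  expect_true(const$normality$degenerate[const$normality$column == "b"])
  expect_true(is.na(const$normality$shapiro_p[const$normality$column == "b"]))
  expect_error(screen_metrics(data.frame(v = c(1, 2))), "n < 3")
  # Shapiro-Wilk delegation sanity: skewed data rejected, column matches stats
  set.seed(4)
  v <- exp(rnorm(100))
  sc2 <- screen_metrics(data.frame(v = v))
  expect_equal(sc2$normality$shapiro_p, shapiro.test(v)$p.value)
})

test_that("Benjamini-Hochberg: hand-worked step-up, ties, singleton, monotonicity", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(numeric(0)), "empty")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  p <- runif(30)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  # rejections at level q match the classic step-up rule
  q <- 0.1
  k <- max(c(0L, which(sort(p) <= q * seq_along(p) / length(p))))
  classic <- p <= if (k == 0) -1 else sort(p)[k]
  expect_equal(adj <= q, classic)
})

test_that("Pillai's trace matches a brute-force eigen computation on a toy dataset", {
  set.seed(6)
  dat <- data.frame(
    y1 = c(1.2, 0.8, 1.9, 2.4, 3.1, 2.2),
    y2 = c(0.3, 0.9, 0.4, 1.8, 1.2, 1.6),
    grp = rep(c("a", "b"), each = 3),
    age = c(7, 9, 11, 8, 10, 12))
  des <- design_spec("model1_hfcs", c("y1", "y2"), clinical = "grp")
  des$predictors <- c("grp", "age")
  res <- manova_pillai(dat, des)
  # oracle: explicit residual cross-products from two least-squares fits
  Y <- as.matrix(dat[c("y1", "y2")])
  X_full <- cbind(1, dat$grp == "b", dat$age - mean(dat$age))
  B <- solve(t(X_full) %*% X_full, t(X_full) %*% Y)
  E <- t(Y - X_full %*% B) %*% (Y - X_full %*% B)
  X_red <- X_full[, -2]
  Br <- solve(t(X_red) %*% X_red, t(X_red) %*% Y)
  H <- t(Y - X_red %*% Br) %*% (Y - X_red %*% Br) - E
  V <- sum(Re(eigen(H %*% solve(H + E))$values))
  expect_equal(res$multivariate$pillai[res$multivariate$term == "grp"], V,
               tolerance = 1e-10)
})

test_that("with a single response the Pillai F reduces to the univariate ANCOVA F", {
  set.seed(8)
  n <- 40
  dat <- data.frame(
    y = rnorm(n),
    hfcs_group = sample(c("1", "2"), n, TRUE),
    limb = rep(c("LAS", "MAS"), n / 2),
    dominance = sample(c("left", "right"), n, TRUE),
    age = runif(n, 7, 18))
  res <- manova_pillai(dat, design_spec("model1_hfcs", "y"))
  fit <- lm(y ~ hfcs_group + limb + dominance + I(age - mean(age)), dat)
  dr <- drop1(fit, test = "F")   # marginal single-term F tests
  for (tm in c("hfcs_group", "limb", "dominance")) {
    expect_equal(res$multivariate$F[res$multivariate$term == tm],
                 dr[tm, "F value"], tolerance = 1e-10)
    expect_equal(res$univariate$F[res$univariate$term == tm],
                 dr[tm, "F value"], tolerance = 1e-10)
  }
})

test_that("Pillai results agree with car::Manova and carry the study's df pattern", {
  coh <- generate_cohort(28, cohort_config(tasks = "small_eight"), seed = 14)
  d <- merge(metrics_table(coh$trials), coh$roster, by = "participant_id")
  des <- design_spec("model1_hfcs", small_eight_responses)
  res <- manova_pillai(d, des)
  d$hfcs_group <- relevel(factor(d$hfcs_group), "1")
  d$limb <- relevel(factor(d$limb), "LAS")
  d$dominance <- relevel(factor(d$dominance), "right")
  d$age_c <- d$age - mean(d$age)
  fit <- lm(cbind(time_s, work_total_j, velocity_pct, accuracy_error_mm) ~
              hfcs_group + limb + dominance + age_c, data = d)
  cm <- car::Manova(fit, type = 2)
  for (i in seq_along(res$multivariate$term)) {
    tm <- c("hfcs_group", "limb", "dominance", "age_c")[i]
    ss <- summary(cm)$multivariate.tests[[tm]]
    V_car <- sum(diag(ss$SSPH %*% solve(ss$SSPH + ss$SSPE)))
    expect_equal(res$multivariate$pillai[i], V_car, tolerance = 1e-10)
  }
  # one-df terms: 56 observations, 4 responses -> F(4, 48), eta_p^2 = V
  expect_equal(res$multivariate$df1, rep(4, 4))
  expect_equal(res$multivariate$df2, rep(48, 4))
  expect_equal(res$multivariate$eta_p_sq, res$multivariate$pillai)
})

test_that("Pillai's V is invariant under invertible recombination of the responses", {
  set.seed(9)
  n <- 30
  dat <- data.frame(matrix(rnorm(3 * n), n, 3))
  names(dat) <- c("r1", "r2", "r3")
  dat$grp <- sample(c("x", "y", "z"), n, TRUE)
  des <- design_spec("model1_hfcs", c("r1", "r2", "r3"), clinical = "grp")
  des$predictors <- "grp"
  v0 <- manova_pillai(dat, des)$multivariate$pillai
  A <- matrix(c(2, 0.5, -1, 0, 1, 3, 1, 0, 1), 3, 3)
  Y2 <- as.matrix(dat[1:3]) %*% A
  dat2 <- dat; dat2[1:3] <- Y2
  expect_equal(manova_pillai(dat2, des)$multivariate$pillai, v0,
               tolerance = 1e-10)
})

test_that("rank-deficient designs fail loudly naming the aliased term", {
  dat <- data.frame(y1 = rnorm(10), y2 = rnorm(10),
                    a = rep(c("u", "v"), 5), b = rep(c("u", "v"), 5),
                    age = 1:10)
  des <- design_spec("model1_hfcs", c("y1", "y2"), clinical = "a")
  des$predictors <- c("a", "b")
  expect_error(manova_pillai(dat, des), "aliased")
  expect_error(design_spec("model1_hfcs", "y", clinical = c("hfcs_group", "macs")),
               "one clinical factor")
})

test_that("Spearman: monotone data, tie handling against an explicit rank oracle, bands", {
  r1 <- spearman_with_category(1:10, (1:10)^3)
  expect_equal(r1$spearman_r, 1)
  expect_equal(r1$category, "very strong")
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8)
  cell <- spearman_with_category(x, y)
  oracle <- oracle_pearson(oracle_avg_ranks(x), oracle_avg_ranks(y))
  expect_equal(cell$spearman_r, oracle, tolerance = 1e-12)
  expect_equal(cell$p, cor.test(x, y, method = "spearman", exact = FALSE)$p.value,
               tolerance = 1e-10)
  # bands partition [0, 1]: half-open low/moderate, high includes 0.90
  band <- vapply(c(0.1, 0.199999, 0.2, 0.399999, 0.4, 0.643, 0.699999, 0.7,
                   0.9, 0.900001, 0.99),
                 planarreach:::spearman_category, "")
  expect_equal(band, c("slight", "slight", "low", "low", "moderate", "moderate",
                       "moderate", "high", "high", "very strong", "very strong"))
  expect_error(spearman_with_category(c(1, 1, 1, 1), 1:4), "variance")
  expect_error(spearman_with_category(1:3, 3:1), "at least 4")
})

test_that("significance stars follow the .05/.01 convention in the correlation table", {
  coh <- generate_cohort(28, cohort_config(tasks = "small_rom"), seed = 23)
  ct <- correlation_table(coh$roster, metrics_table(coh$trials))
  expect_true(all(ct$stars[ct$p < 0.01] == "**"))
  expect_true(all(ct$stars[ct$p >= 0.05] == ""))
  expect_true(all(abs(ct$spearman_r) <= 1))
})
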