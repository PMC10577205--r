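test_that("Kruskal-Wallis: hand-ranked example and tie handling", {
  # disjoint groups {1,2,3} vs {4,5,6}: H = (12/(6*7))(6^2/3 + 15^2/3) - 3*7
  kw <- kruskal_wallis(c(1, 2, 3), c(4, 5, 6))
  expect_equal(kw$statistic, 12 / 42 * (36 / 3 + 225 / 3) - 21)
  expect_equal(kw$df, 1L)

  # symmetric ties: H = 0
  kw0 <- kruskal_wallis(c(1, 2), c(1, 2))
  expect_equal(kw0$statistic, 0)

  # rank invariance under a common shift
  a <- c(3, 9, 1, 7); b <- c(2, 8, 5, 6)
  expect_equal(kruskal_wallis(a + 100, b + 100)$statistic,
               kruskal_wallis(a, b)$statistic)

  # degenerate: identical values in both groups
  kd <- kruskal_wallis(c(5, 5, 5), c(5, 5))
  expect_true(kd$degenerate)
  expect_equal(kd$statistic, 0)
  expect_equal(kd$p_value, 1)

  expect_error(kruskal_wallis(1, c(1, 2)), "at least two")
})

test_that("Kruskal-Wallis equals the brute-force midrank formula, n <= 12", {
  set.seed(77)
  for (k in 1:200) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    # integer draws to force ties
    a <- sample(1:5, na, replace = TRUE)
    b <- sample(1:5, nb, replace = TRUE)
    if (length(unique(c(a, b))) == 1) next
    expect_lt(abs(kruskal_wallis(a, b)$statistic - oracle_kruskal_h(a, b)),
              1e-10)
  }
})

test_that("Spearman: textbook cases and monotone invariance", {
  expect_equal(spearman(1:6, (1:6)^2)$rho, 1)
  expect_equal(spearman(1:5, 5:1)$rho, -1)
  # d = (1,1,0): rho = 1 - 6*2/(3*8) = 0.5
  expect_equal(spearman(c(1, 2, 3), c(2, 1, 3))$rho, 0.5)

  set.seed(8)
  x <- rnorm(30); y <- rnorm(30)
  r1 <- spearman(x, y)
  r2 <- spearman(exp(x), qlogis(plogis(y))^3)
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)

  const <- spearman(rep(1, 10), rnorm(10))
  expect_true(const$undefined)
  expect_true(is.na(const$rho))
  expect_error(spearman(1:2, 1:2), "three")
})

test_that("Spearman exact permutation option works at small n", {
  r <- spearman(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5), exact = TRUE)
  expect_equal(r$rho, 0.8)
  expect_true(r$p_value > 0 && r$p_value < 1)
})

test_that("OLS biomarker fit matches the normal-equation oracle", {
  x1 <- c(0, 1, 2, 3); x2 <- c(1, 0, 1, 0); y <- c(1, 3, 5, 7)
  d <- data.frame(bbi = y, amp = x1, ipl = x2)
  fit <- fit_biomarker_model(d, "bbi", c("amp", "ipl"))
  oracle <- oracle_ols(cbind(x1, x2), y)
  expect_equal(unname(fit$coefficients$estimate), unname(oracle$beta),
               tolerance = 1e-9)
  expect_equal(fit$r2, 1)

  set.seed(19)
  n <- 35
  d2 <- data.frame(amp = rnorm(n), ipl = rnorm(n))
  d2$bbi <- 40 + 2 * d2$amp + 0.5 * d2$ipl + rnorm(n, 0, 5)
  fit2 <- fit_biomarker_model(d2, "bbi", c("amp", "ipl"))
  o2 <- oracle_ols(cbind(d2$amp, d2$ipl), d2$bbi)
  expect_equal(fit2$r2, o2$r2, tolerance = 1e-12)
  expect_equal(fit2$adj_r2, o2$adj_r2, tolerance = 1e-12)
  expect_equal(fit2$df1, 2)
  expect_equal(fit2$df2, n - 3)
})

test_that("OLS degenerate cases: perfect fit, collinearity, tiny n", {
  d <- data.frame(y = 1:6, x = 1:6, z = c(2, 4, 6, 8, 10, 12))
  expect_equal(fit_biomarker_model(d, "y", "x")$r2, 1)
  expect_error(fit_biomarker_model(d, "y", c("x", "z")), "collinear")
  expect_error(fit_biomarker_model(d[1:3, ], "y", c("x", "z")),
               "complete cases")
})

test_that("mixed logistic model recovers a known group odds ratio", {
  set.seed(101)
  d <- simulate_error_trials(n_subj = 40, n_trials = 128, p_base = 0.06,
                             or_group = 2.5, sd_subj = 0.5)
  fit <- fit_error_model(d, "commission")
  g <- fit$fixed[fit$fixed$term == "groupburnout", ]
  expect_gt(g$or, 1.3)
  expect_true(g$ci_lo < 2.5 & 2.5 < g$ci_hi)
  expect_gt(fit$ranef_variance, 0)
})

test_that("zero random-effect data reproduce plain logistic regression", {
  set.seed(33)
  d <- simulate_error_trials(n_subj = 60, n_trials = 128, p_base = 0.08,
                             or_group = 1.5, sd_subj = 0)
  fit <- suppressMessages(fit_error_model(d, "commission"))
  d2 <- d[d$condition == "NoGo", ]
  d2$group <- factor(d2$group, levels = c("non_burnout", "burnout"))
  plain <- glm(I(class_commission == "commission_error") ~
                 group + stimulator + distractor,
               data = d2, family = binomial())
  expect_lt(max(abs(log(fit$fixed$or) - unname(coef(plain)[-1]))), 1e-3)
})

test_that("all-correct outcomes raise a separation error", {
  sess <- generate_session(2, n_practice = 0, n_test = 1)
  resp <- data.frame(
    pressed = sess$condition == "Go",
    button = ifelse(sess$condition == "Go", sess$triangle, "none"),
    rt_ms = ifelse(sess$condition == "Go", 400, NA),
    stringsAsFactors = FALSE)
  out <- classify_outcomes(sess, resp)
  out$subject <- "s1"; out$group <- "burnout"
  expect_error(fit_error_model(out, "total"), "separation")
})

test_that("full analysis flags a missing group as a partial report", {
  set.seed(2)
  cohort <- simulate_cohort(run_config(seed = 2, n_burnout = 3,
                                       n_non_burnout = 0,
                                       conditions = "Go"))
  rep <- suppressMessages(run_full_analysis(cohort))
  expect_true(rep$partial)
  expect_true(length(rep$gaps) > 0)
})
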