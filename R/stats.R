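#' Two-group Kruskal-Wallis rank-sum test
#'
#' Rank-based H statistic with midranks for ties and the tie correction;
#' with two groups df = 1 and the p-value is chi-squared. Group medians and
#' IQRs are reported alongside. If every value across both groups is
#' identical the statistic is undefined; 0 is returned with `p = 1` and a
#' degenerate flag.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 2).
#' @param labels Group labels for the reported medians.
#' @return A list of class `chisq_result`: `statistic`, `df`, `p_value`,
#'   `medians`, `iqrs`, `n`, `degenerate`.
#' @export
kruskal_wallis <- function(values_a, values_b, labels = c("a", "b")) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least two values")
  meds <- setNames(c(median(values_a), median(values_b)), labels)
  iqrs <- setNames(c(IQR(values_a), IQR(values_b)), labels)
  n <- c(length(values_a), length(values_b))
  degenerate <- length(unique(c(values_a, values_b))) == 1
  if (degenerate) {
    stat <- 0; p <- 1
  } else {
    kt <- kruskal.test(list(values_a, values_b))
    stat <- unname(kt$statistic); p <- kt$p.value
  }
  structure(list(statistic = stat, df = 1L, p_value = p, medians = meds,
                 iqrs = iqrs, n = setNames(n, labels),
                 degenerate = degenerate),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.3f, df = %d, p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$degenerate) " (degenerate: all values tied)" else ""))
  for (g in names(x$medians))
    cat(sprintf("  %s: median %.4g (IQR %.4g), n = %d\n",
                g, x$medians[g], x$iqrs[g], x$n[g]))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; the p-value uses the t approximation
#' (appropriate at the cohort sizes analysed here). For n <= 10 without
#' ties an exact permutation p-value is available via `exact = TRUE`.
#' Constant input is flagged and returns `NA` for rho.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @param exact Use the exact permutation distribution (small n, no ties).
#' @return A list of class `rho_result`: `rho`, `p_value`, `n`,
#'   `undefined`.
#' @export
spearman <- function(x, y, exact = FALSE) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least three complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(structure(list(rho = NA_real_, p_value = NA_real_,
                          n = length(x), undefined = TRUE),
                     class = "rho_result"))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), undefined = FALSE),
            class = "rho_result")
}

#' @export
print.rho_result <- function(x, ...) {
  if (x$undefined) cat("Spearman rho undefined (constant input), n =", x$n, "\n")
  else cat(sprintf("Spearman rho = %.3f, p = %.4g, n = %d\n",
                   x$rho, x$p_value, x$n))
  invisible(x)
}

#' Mixed-effects logistic error model
#'
#' Fits a generalized mixed-effects logistic regression for one error type
#' with a per-subject random intercept (Laplace approximation via
#' [lme4::glmer()]) and group, stimulator status, and emotional valence as
#' fixed effects. The outcome is dichotomised per type over its domain:
#' total errors over all trials, incorrect and missing responses over Go
#' trials, commission errors over NoGo trials. Per-trial Bernoulli rows
#' are aggregated to binomial counts per subject and fixed-effect cell
#' before fitting (the likelihood is identical).
#'
#' @param outcomes Classified trial table from [classify_outcomes()] with a
#'   `subject` and `group` column (practice trials should be excluded
#'   beforehand or via `practice_excluded`).
#' @param error_type One of `"total"`, `"incorrect"`, `"miss"`,
#'   `"commission"`.
#' @param practice_excluded Drop practice-block rows first.
#' @return A list of class `or_table`: per fixed effect the odds ratio with
#'   Wald 95% CI, the random-intercept variance, the number of subjects and
#'   trials, and a `separation` flag (unbounded CIs are reported as
#'   `Inf`/0 when the model is separated).
#' @export
fit_error_model <- function(outcomes,
                            error_type = c("total", "incorrect", "miss",
                                           "commission"),
                            practice_excluded = TRUE) {
  error_type <- match.arg(error_type)
  d <- outcomes
  if (practice_excluded && "is_practice" %in% names(d))
    d <- d[!d$is_practice, , drop = FALSE]
  d <- switch(error_type,
    total      = transform(d, err = class_total == "error"),
    incorrect  = transform(d[d$condition == "Go", ],
                           err = class_incorrect == "incorrect"),
    miss       = transform(d[d$condition == "Go", ],
                           err = class_miss == "miss"),
    commission = transform(d[d$condition == "NoGo", ],
                           err = class_commission == "commission_error"))
  if (nrow(d) == 0) stop("no trials in the domain of this error type")
  if (all(c("burnout", "non_burnout") %in% d$group))
    d$group <- factor(d$group, levels = c("non_burnout", "burnout"))
  k <- sum(d$err)
  if (k == 0 || k == nrow(d))
    stop("complete separation: all outcomes are ",
         if (k == 0) "'correct'" else "'error'",
         " for error type '", error_type, "'")
  agg <- aggregate(err ~ subject + group + stimulator + distractor,
                   data = d, FUN = function(v) c(k = sum(v), n = length(v)))
  agg <- data.frame(agg[, c("subject", "group", "stimulator", "distractor")],
                    k = agg$err[, "k"], n = agg$err[, "n"])
  fit <- lme4::glmer(cbind(k, n - k) ~ group + stimulator + distractor +
                       (1 | subject),
                     data = agg, family = binomial())
  est <- lme4::fixef(fit)[-1]
  se <- sqrt(diag(as.matrix(vcov(fit))))[-1]
  unbounded <- se > 10
  tab <- data.frame(
    term = names(est),
    or = exp(unname(est)),
    ci_lo = ifelse(unbounded, 0, exp(unname(est) - 1.96 * se)),
    ci_hi = ifelse(unbounded, Inf, exp(unname(est) + 1.96 * se)),
    stringsAsFactors = FALSE
  )
  structure(list(error_type = error_type, fixed = tab,
                 ranef_variance = unname(lme4::VarCorr(fit)$subject[1]),
                 n_subjects = length(unique(d$subject)),
                 n_trials = nrow(d),
                 separation = any(unbounded), fit = fit),
            class = "or_table")
}

#' @export
print.or_table <- function(x, ...) {
  cat("Mixed logistic model for", x$error_type, "errors -",
      x$n_trials, "trials,", x$n_subjects, "subjects\n")
  cat(sprintf("  random-intercept variance (subject): %.4f\n",
              x$ranef_variance))
  print(x$fixed, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Linear biomarker regression
#'
#' Ordinary least squares of a questionnaire response on ERP predictors
#' (centroparietal P3 amplitude with either P3 latency or the N2-P3
#' interpeak latency). Complete cases only; a rank-deficient predictor
#' matrix (collinear predictors) is refused.
#'
#' @param data Data frame holding the response and predictor columns.
#' @param response Name of the response column (e.g. BBI-15 or the
#'   BRIEF-A metacognition index).
#' @param predictors Character vector of predictor column names.
#' @return A list of class `regression_summary`: `coefficients` (estimate,
#'   SE, t, p per term), `f_statistic`, `df1`, `df2`, `p_value`, `r2`,
#'   `adj_r2`, `n`.
#' @export
fit_biomarker_model <- function(data, response, predictors) {
  stopifnot(all(c(response, predictors) %in% names(data)))
  d <- data[complete.cases(data[, c(response, predictors)]),
            c(response, predictors), drop = FALSE]
  if (nrow(d) <= length(predictors) + 1)
    stop("need more complete cases than predictors plus one")
  X <- as.matrix(d[, predictors, drop = FALSE])
  if (qr(cbind(1, X))$rank < length(predictors) + 1)
    stop("collinear predictors: rank-deficient fit refused")
  fml <- as.formula(paste(response, "~",
                          paste(sprintf("`%s`", predictors), collapse = " + ")))
  fit <- lm(fml, data = d)
  s <- summary(fit)
  co <- as.data.frame(s$coefficients)
  names(co) <- c("estimate", "se", "t", "p")
  co <- cbind(term = rownames(co), co)
  rownames(co) <- NULL
  structure(list(response = response, predictors = predictors,
                 coefficients = co,
                 f_statistic = unname(s$fstatistic["value"]),
                 df1 = unname(s$fstatistic["numdf"]),
                 df2 = unname(s$fstatistic["dendf"]),
                 p_value = unname(pf(s$fstatistic["value"],
                                     s$fstatistic["numdf"],
                                     s$fstatistic["dendf"],
                                     lower.tail = FALSE)),
                 r2 = s$r.squared, adj_r2 = s$adj.r.squared,
                 n = nrow(d), fit = fit),
            class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("OLS: %s ~ %s  (n = %d)\n", x$response,
              paste(x$predictors, collapse = " + "), x$n))
  cat(sprintf("  F(%d, %d) = %.2f, p = %.4g, R2 = %.3f, adj. R2 = %.3f\n",
              x$df1, x$df2, x$f_statistic, x$p_value, x$r2, x$adj_r2))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}
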