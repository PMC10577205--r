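#' Sample subject questionnaire profiles
#'
#' Draws one or more subject profiles for a group from the calibration's
#' truncated-normal questionnaire model: each scale is drawn from a normal
#' with the group's mean and SD and clamped to the scale bounds (BBI-15 in
#' 15-90, BDI-21 in 0-63, BRIEF-A T-scores in 20-100). At the calibrated
#' means the clamping shifts are negligible (< 2% of an SD).
#'
#' @param group `"burnout"` or `"non_burnout"`.
#' @param calib A [cohort_calibration()].
#' @param n Number of profiles.
#' @param subject_ids Optional character ids (default `"<group>_<i>"`).
#' @return Data frame with one row per subject: `subject`, `group`, `sex`,
#'   `age_years`, `bbi15`, `bdi21`, `brief_bri`, `brief_mi`, `brief_gec`,
#'   and `z_bbi15`, the BBI-15 z-score within its group (used by the
#'   profile-to-ERP coupling).
#' @export
sample_profile <- function(group, calib = cohort_calibration(), n = 1,
                           subject_ids = NULL) {
  if (!group %in% c("burnout", "non_burnout"))
    stop("unknown group label: ", group)
  stopifnot(n >= 1)
  draw <- function(scale) {
    p <- calib$questionnaires[[scale]][[group]]
    b <- calib$questionnaires[[scale]]$bounds
    pmin(b[2], pmax(b[1], rnorm(n, p["mean"], p["sd"])))
  }
  bbi <- draw("bbi15")
  qb <- calib$questionnaires$bbi15[[group]]
  if (is.null(subject_ids))
    subject_ids <- sprintf("%s_%02d", group, seq_len(n))
  data.frame(
    subject = subject_ids,
    group = group,
    sex = ifelse(runif(n) < calib$p_female[[group]], "F", "M"),
    age_years = draw("age_years"),
    bbi15 = bbi,
    bdi21 = draw("bdi21"),
    brief_bri = draw("brief_bri"),
    brief_mi = draw("brief_mi"),
    brief_gec = draw("brief_gec"),
    z_bbi15 = (bbi - qb["mean"]) / qb["sd"],
    stringsAsFactors = FALSE
  )
}

#' Sample normative BRIEF-A T-scores
#'
#' Draws T-scores from the normative population model: mean 50, SD 10
#' (clamped to the 20-100 T-score range; at 3 SD the clamping is
#' negligible). Scores above 65 (1.5 SD) are conventionally abnormal.
#'
#' @param n Number of draws (>= 1).
#' @param sd Population SD (default 10; 0 gives the degenerate constant 50).
#' @return Numeric vector of length `n`.
#' @export
normative_tscore_sample <- function(n, sd = 10) {
  if (length(n) != 1 || n < 1) stop("n must be a single integer >= 1")
  pmin(100, pmax(20, rnorm(n, 50, sd)))
}

#' Simulate behavioural responses for one subject
#'
#' For each trial, draws the response from the calibrated per-type error
#' model. On Go trials the outcome is correct / incorrect / miss with
#' per-trial probabilities; on NoGo trials a commission press occurs with
#' the commission probability. A shared per-subject intercept `u` on the
#' logit scale (SD `calib$subject_logit_sd`, drawn once per call unless
#' supplied) shifts all three error probabilities, giving the mixed
#' logistic error model a true random effect to recover. Reaction times on
#' pressed trials are log-normal with the group's median and SD.
#'
#' @param profile One-row data frame from [sample_profile()].
#' @param trials Trial table from [generate_session()].
#' @param calib A [cohort_calibration()].
#' @param subject_logit Optional fixed per-subject intercept (logit scale).
#' @return Data frame row-aligned with `trials`: `pressed`, `button`,
#'   `rt_ms`.
#' @export
simulate_behavior <- function(profile, trials, calib = cohort_calibration(),
                              subject_logit = NULL) {
  group <- profile$group[1]
  p <- calib$error_probs[[group]]
  if (is.null(subject_logit))
    subject_logit <- rnorm(1, 0, calib$subject_logit_sd)
  shift <- function(prob) plogis(qlogis(prob) + subject_logit)
  p_inc <- if (p["incorrect"] > 0) shift(p["incorrect"]) else 0
  p_miss <- if (p["miss"] > 0) shift(p["miss"]) else 0
  p_com <- if (p["commission"] > 0) shift(p["commission"]) else 0

  n <- nrow(trials)
  go <- trials$condition == "Go"
  u <- runif(n)
  pressed <- logical(n)
  button <- rep("none", n)
  # Go: miss with p_miss; else press, wrong button with p_inc/(1-p_miss)
  miss <- go & u < p_miss
  pressed[go & !miss] <- TRUE
  wrong <- go & pressed & (runif(n) < p_inc / max(1 - p_miss, 1e-12))
  correct_btn <- ifelse(trials$triangle == "up", "up", "down")
  wrong_btn <- ifelse(trials$triangle == "up", "down", "up")
  button[go & pressed] <- ifelse(wrong[go & pressed],
                                 wrong_btn[go & pressed],
                                 correct_btn[go & pressed])
  # NoGo: commission press (button follows the triangle as a prepotent act)
  com <- !go & u < p_com
  pressed[com] <- TRUE
  button[com] <- correct_btn[com]

  rt <- rep(NA_real_, n)
  g <- calib$rt[[group]]
  sdlog <- g["sd_ms"] / g["median_ms"]
  rt[pressed] <- rlnorm(sum(pressed), log(g["median_ms"]), sdlog)
  data.frame(pressed = pressed, button = button, rt_ms = rt,
             stringsAsFactors = FALSE)
}

#' @importFrom stats plogis qlogis
NULL
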