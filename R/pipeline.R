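#' Run configuration for the end-to-end pipeline
#'
#' Collects every tunable of the simulate-extract-analyze chain with its
#' default. All randomness derives from `seed`: per-subject seeds are drawn
#' once from it and recorded, so any subject can be re-simulated in
#' isolation.
#'
#' @param seed Master seed (integer).
#' @param n_burnout,n_non_burnout Cohort sizes (defaults 18 and 17, the
#'   ERP-eligible group sizes).
#' @param n_practice,n_test Blocks per session.
#' @param conditions Trial conditions to simulate EEG for (`"Go"`,
#'   `"NoGo"`).
#' @param couple Couple generative P3 amplitude to the BBI-15 score.
#' @param subject_sd Scale on between-subject ERP parameter spread
#'   (0 = every subject at the group calibration defaults).
#' @param blinks Inject blink artifacts.
#' @param low_hz,high_hz Filter band edges (Hz).
#' @param threshold_uv Peak-to-peak rejection threshold (uV).
#' @param min_epochs Minimum artifact-free epochs per condition.
#' @param out_dir Optional output directory for [run_end_to_end()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_burnout = 18, n_non_burnout = 17,
                       n_practice = 4, n_test = 4,
                       conditions = c("Go", "NoGo"),
                       couple = TRUE, subject_sd = 1, blinks = TRUE,
                       low_hz = 0.1, high_hz = 40, threshold_uv = 80,
                       min_epochs = 50, out_dir = NULL) {
  stopifnot(n_burnout >= 0, n_non_burnout >= 0, threshold_uv > 0,
            min_epochs >= 1, low_hz > 0, low_hz < high_hz, high_hz < 250)
  structure(as.list(environment()), class = "run_config")
}

#' Simulate and extract a full cohort
#'
#' For each subject: draw a questionnaire profile, generate an Executive RT
#' session, simulate behavioural responses and per-trial EEG epochs with
#' the subject's (optionally profile-coupled) ERP parameters, inject blink
#' artifacts, and run the extraction chain (re-reference, band-pass,
#' peak-to-peak rejection, condition averaging with the minimum-epoch rule,
#' pooled peak measurement). Subjects whose epochs are all rejected or
#' with no eligible condition average are excluded with a logged reason.
#'
#' @param config A [run_config()].
#' @param calib A [cohort_calibration()].
#' @return A list of class `cohort_data`: `profiles`, `outcomes`
#'   (classified trials, all subjects), `measures` (per subject x condition
#'   x pool), `exclusions` (subject, reason), `subject_seeds`, `config`.
#' @export
simulate_cohort <- function(config = run_config(),
                            calib = cohort_calibration()) {
  set.seed(config$seed)
  n_total <- config$n_burnout + config$n_non_burnout
  groups <- rep(c("burnout", "non_burnout"),
                c(config$n_burnout, config$n_non_burnout))
  subject_seeds <- sample.int(.Machine$integer.max - 1, n_total)
  profiles <- vector("list", n_total)
  outcomes <- vector("list", n_total)
  measures <- vector("list", n_total)
  exclusions <- list()
  for (i in seq_len(n_total)) {
    set.seed(subject_seeds[i])
    id <- sprintf("S%02d_%s", i, groups[i])
    prof <- sample_profile(groups[i], calib, subject_ids = id)
    sess <- generate_session(seed = NULL, n_practice = config$n_practice,
                             n_test = config$n_test)
    resp <- simulate_behavior(prof, sess, calib)
    out <- classify_outcomes(sess, resp)
    out$subject <- id; out$group <- groups[i]
    cfg_i <- subject_erp_params(prof, calib, couple = config$couple,
                                subject_sd = config$subject_sd)
    test_trials <- sess[!sess$is_practice &
                          sess$condition %in% config$conditions, ,
                        drop = FALSE]
    ep <- simulate_epochs(test_trials, cfg_i, subject_id = id)
    if (config$blinks) ep <- inject_artifacts(ep, cfg_i)
    ext <- tryCatch(
      extract_subject(ep, config$low_hz, config$high_hz,
                      config$threshold_uv, config$min_epochs),
      error = function(e) e)
    profiles[[i]] <- prof
    outcomes[[i]] <- out
    if (inherits(ext, "error")) {
      exclusions[[id]] <- conditionMessage(ext)
    } else if (!any(ext$measures$eligible)) {
      exclusions[[id]] <- sprintf(
        "no condition reached %d artifact-free epochs", config$min_epochs)
      m <- ext$measures; m$group <- groups[i]
      measures[[i]] <- m
    } else {
      m <- ext$measures; m$group <- groups[i]
      measures[[i]] <- m
    }
  }
  structure(list(
    profiles = do.call(rbind, profiles),
    outcomes = do.call(rbind, outcomes),
    measures = do.call(rbind, measures),
    exclusions = if (length(exclusions))
      data.frame(subject = names(exclusions),
                 reason = unlist(exclusions), row.names = NULL)
    else data.frame(subject = character(), reason = character()),
    subject_seeds = subject_seeds,
    config = config
  ), class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("<cohort_data>", nrow(x$profiles), "subjects (",
      sum(x$profiles$group == "burnout"), "burnout /",
      sum(x$profiles$group == "non_burnout"), "non-burnout ),",
      nrow(x$exclusions), "excluded from ERP analysis\n")
  invisible(x)
}

#' Simulate, extract, and analyse in one call
#'
#' Runs [simulate_cohort()] followed by [run_full_analysis()] and, if
#' `config$out_dir` is set, writes the trial, measurement, and profile
#' tables plus a machine-readable JSON summary with provenance (seed,
#' config, package version). Identical config and seed produce a
#' byte-identical summary.
#'
#' @param config A [run_config()].
#' @param calib A [cohort_calibration()].
#' @return A list with `cohort` (the `cohort_data`) and `report` (the
#'   `erp_report`); invisibly the paths written, as attribute `paths`.
#' @export
run_end_to_end <- function(config = run_config(),
                           calib = cohort_calibration()) {
  cohort <- simulate_cohort(config, calib)
  report <- run_full_analysis(cohort)
  paths <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- write_report_bundle(cohort, report, config$out_dir)
  }
  structure(list(cohort = cohort, report = report), paths = paths)
}

#' Parameter-recovery study for the pooled centroparietal P3 and IPL
#'
#' Simulates `n_subjects` subjects at one group's ERP calibration defaults
#' (no between-subject parameter spread, default noise and blink rate,
#' Go-condition epochs from a full four-test-block session), runs the full
#' extraction chain, and summarises the across-subject medians of the
#' pooled centroparietal Go P3 amplitude and N2-P3 interpeak latency. This
#' is the package's check that the measurement chain recovers the
#' generative component parameters under realistic noise.
#'
#' @param group `"burnout"` or `"non_burnout"`.
#' @param n_subjects Number of simulated subjects (default: the study's
#'   ERP-eligible group sizes, 18 and 17).
#' @param seed Master seed.
#' @param min_epochs Minimum artifact-free epochs per condition.
#' @return A list with `per_subject` (subject, amplitude, IPL, clean-epoch
#'   count), `median_p3_amplitude_uv`, `median_ipl_ms`, `n`.
#' @export
erp_recovery_study <- function(group, n_subjects = if (group == "burnout") 18 else 17,
                               seed = 1, min_epochs = 50) {
  cfg <- run_config(seed = seed,
                    n_burnout = if (group == "burnout") n_subjects else 0,
                    n_non_burnout = if (group == "burnout") 0 else n_subjects,
                    conditions = "Go", couple = FALSE, subject_sd = 0,
                    min_epochs = min_epochs)
  cohort <- simulate_cohort(cfg)
  cp <- cohort$measures[cohort$measures$pool == "centroparietal" &
                          cohort$measures$condition == "Go" &
                          cohort$measures$eligible, , drop = FALSE]
  list(per_subject = cp[, c("subject", "p3_amplitude_uv", "p3_latency_ms",
                            "n2_p3_ipl_ms", "n_epochs")],
       median_p3_amplitude_uv = median(cp$p3_amplitude_uv),
       median_ipl_ms = median(cp$n2_p3_ipl_ms),
       n = nrow(cp))
}

#' Correlation-recovery study for the BBI-15 / P3-amplitude coupling
#'
#' Simulates replicate two-group cohorts (18 burnout + 17 non-burnout by
#' default) under the default profile-to-ERP coupling, runs the full
#' extraction chain on Go-condition epochs, and computes the Spearman
#' correlation between the extracted pooled centroparietal Go P3 amplitude
#' and the BBI-15 score within each replicate cohort.
#'
#' @param n_replicates Number of replicate cohorts.
#' @param seed Master seed (each replicate derives its own seed).
#' @param n_burnout,n_non_burnout Group sizes per cohort.
#' @return A list with `rhos` (one per replicate) and `mean_rho`.
#' @export
coupling_recovery_study <- function(n_replicates = 50, seed = 1,
                                    n_burnout = 18, n_non_burnout = 17) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_replicates)
  rhos <- vapply(rep_seeds, function(s) {
    cohort <- simulate_cohort(run_config(
      seed = s, n_burnout = n_burnout, n_non_burnout = n_non_burnout,
      conditions = "Go"))
    cp <- cohort$measures[cohort$measures$pool == "centroparietal" &
                            cohort$measures$condition == "Go" &
                            cohort$measures$eligible, , drop = FALSE]
    d <- merge(cp, cohort$profiles, by = "subject")
    spearman(d$p3_amplitude_uv, d$bbi15)$rho
  }, 0)
  list(rhos = rhos, mean_rho = mean(rhos))
}
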