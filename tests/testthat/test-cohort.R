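test_that("profile draws recover the calibrated group means", {
  set.seed(11)
  calib <- cohort_calibration()
  b <- sample_profile("burnout", calib, n = 4000)
  nb <- sample_profile("non_burnout", calib, n = 4000)
  expect_equal(mean(b$bbi15), 60.06, tolerance = 0.01)
  expect_equal(mean(b$bdi21), 15.89, tolerance = 0.03)
  expect_equal(mean(nb$brief_mi), 47.47, tolerance = 0.02)
  expect_true(all(b$bbi15 >= 15 & b$bbi15 <= 90))
  expect_true(all(nb$bdi21 >= 0 & nb$bdi21 <= 63))
  expect_error(sample_profile("sometimes_tired"), "unknown group")
})

test_that("zero-SD calibration degenerates to the mean", {
  calib <- cohort_calibration()
  calib$questionnaires$bbi15$burnout["sd"] <- 0
  p <- sample_profile("burnout", calib, n = 5)
  expect_true(all(p$bbi15 == 60.06))
})

test_that("normative T-scores have mean 50, SD 10, and the 1.5-SD tail", {
  set.seed(21)
  x <- normative_tscore_sample(100000)
  expect_equal(mean(x), 50, tolerance = 0.002)  # absolute ~0.1
  expect_equal(sd(x), 10, tolerance = 0.01)
  expect_equal(mean(x > 65), pnorm(1.5, lower.tail = FALSE),
               tolerance = 0.05)
  expect_equal(normative_tscore_sample(1, sd = 0), 50)
  expect_error(normative_tscore_sample(0), "n must be")
})

test_that("behaviour simulation: zero error probabilities give a clean run", {
  calib <- cohort_calibration()
  calib$error_probs$burnout[] <- 0
  set.seed(3)
  prof <- sample_profile("burnout", calib)
  sess <- generate_session(3)
  out <- classify_outcomes(sess, simulate_behavior(prof, sess, calib))
  expect_true(all(out$outcome == "correct"))
})

test_that("pooled commission rate matches the Bernoulli probability", {
  calib <- cohort_calibration()
  calib$error_probs$burnout <- c(incorrect = 0, miss = 0, commission = 0.01)
  calib$subject_logit_sd <- 0
  set.seed(8)
  prof <- sample_profile("burnout", calib)
  hits <- 0; n <- 0
  for (k in 1:30) {
    sess <- generate_session(k)
    out <- classify_outcomes(sess, simulate_behavior(prof, sess, calib,
                                                     subject_logit = 0))
    hits <- hits + sum(out$outcome == "commission")
    n <- n + sum(out$condition == "NoGo")
  }
  expect_equal(hits / n, 0.01, tolerance = 0.4)
})

test_that("per-type error rates sit near the calibrated medians", {
  set.seed(13)
  calib <- cohort_calibration()
  sess <- generate_session(1)
  rates <- t(replicate(40, {
    prof <- sample_profile("burnout", calib)
    out <- classify_outcomes(sess, simulate_behavior(prof, sess, calib))
    out <- out[!out$is_practice, ]
    c(inc = mean(out$outcome[out$condition == "Go"] == "incorrect"),
      com = mean(out$outcome[out$condition == "NoGo"] == "commission"))
  }))
  # medians of per-subject percentages near Table-calibrated values
  expect_equal(100 * median(rates[, "inc"]), 0.98, tolerance = 0.6)
  expect_equal(100 * median(rates[, "com"]), 1.17, tolerance = 0.6)
})

test_that("epochs have the exact segment geometry", {
  cfg <- quiet_config()
  ep <- condition_epochs(cfg, "Go", n = 3)
  expect_equal(length(ep$times), 1000)
  expect_equal(ep$times[1], -200)
  expect_equal(ep$times[1000], 1798)
  expect_equal(unique(diff(ep$times)), 2)
  expect_equal(dim(ep$data), c(1000, 13, 3))
})

test_that("noiseless epochs carry the configured component geometry", {
  cfg <- quiet_config("burnout")
  ep <- condition_epochs(cfg, "Go", n = 1)
  tr <- ep$data[, "CPz", 1]
  w <- ep$times >= 600 & ep$times <= 800
  expect_equal(max(tr[w]), 9.89)
  expect_equal(ep$times[w][which.max(tr[w])], 728)
  fz <- ep$data[, "Fz", 1]
  w2 <- ep$times >= 500 & ep$times <= 650
  expect_equal(min(fz[w2]), -4)
  expect_equal(ep$times[w2][which.min(fz[w2])], 540)
  # mastoids silent by construction
  expect_true(all(ep$data[, c("TP9", "TP10"), ] == 0))
})

test_that("condition average of noiseless epochs equals a single epoch", {
  cfg <- quiet_config()
  ep <- condition_epochs(cfg, "Go", n = 60)
  avg <- average_conditions(ep, min_epochs = 50)$Go
  one <- baseline_correct(ep[1])
  expect_equal(avg$data, one$data[, , 1], tolerance = 1e-12)
  expect_true(avg$eligible)
})

test_that("window-incompatible configs are refused", {
  cfg <- quiet_config()
  cfg$components$Go["n2_latency_ms"] <- 400
  expect_error(validate_erp_config(cfg), "N2 latency")
  cfg <- quiet_config()
  cfg$components$Go["n2_latency_ms"] <- 630
  cfg$components$Go["p3_latency_ms"] <- 610
  expect_error(validate_erp_config(cfg), "P3 latency must exceed")
})

test_that("blink injection: rate 0 no-op, rate 1 everywhere over 80 uV", {
  cfg <- quiet_config()
  ep <- condition_epochs(cfg, "Go", n = 10)
  cfg0 <- cfg; cfg0$blink_rate <- 0
  set.seed(1)
  expect_identical(inject_artifacts(ep, cfg0), ep)
  cfg1 <- cfg; cfg1$blink_rate <- 1
  set.seed(1)
  all_blink <- inject_artifacts(ep, cfg1)
  expect_true(all(all_blink$info$blink))
  p2p_fp1 <- apply(all_blink$data[, "Fp1", ], 2, function(v) max(v) - min(v))
  expect_true(all(p2p_fp1 > 80))
  cfg_low <- cfg; cfg_low$blink_amplitude_uv <- 50
  expect_error(inject_artifacts(ep, cfg_low), "exceed 80")
})

test_that("blink count follows the binomial mean", {
  cfg <- quiet_config()
  cfg$blink_rate <- 0.2
  ep <- condition_epochs(cfg, "Go", n = 320)
  set.seed(99)
  flagged <- sum(inject_artifacts(ep, cfg)$info$blink)
  expect_gt(flagged, 64 - 3 * sqrt(320 * 0.2 * 0.8))
  expect_lt(flagged, 64 + 3 * sqrt(320 * 0.2 * 0.8))
})

test_that("epoch simulation is deterministic given the RNG state", {
  cfg <- erp_gen_config("burnout")
  tr <- test_trials(4)[1:20, ]
  set.seed(77); a <- simulate_epochs(tr, cfg)
  set.seed(77); b <- simulate_epochs(tr, cfg)
  expect_identical(a, b)
})

test_that("generative coupling propagates BBI into P3 amplitude", {
  set.seed(31)
  calib <- cohort_calibration()
  n <- 2000
  prof <- rbind(sample_profile("burnout", calib, n = n / 2),
                sample_profile("non_burnout", calib, n = n / 2))
  amp <- vapply(seq_len(n), function(i)
    unname(subject_erp_params(prof[i, ], calib)$components$Go["p3_amplitude_uv"]), 0)
  rho <- cor(amp, prof$bbi15, method = "spearman")
  expect_equal(rho, 0.45, tolerance = 0.2)
  # without coupling only the group separation remains
  amp0 <- vapply(seq_len(n), function(i)
    unname(subject_erp_params(prof[i, ], calib, couple = FALSE)$components$Go["p3_amplitude_uv"]), 0)
  expect_lt(cor(amp0, prof$bbi15, method = "spearman"), rho)
})
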