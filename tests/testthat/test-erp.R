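make_epochs <- function(data3d, channels, times = NULL) {
  ns <- dim(data3d)[1]
  if (is.null(times)) times <- seq(-200, by = 2, length.out = ns)
  epoch_set(data3d, channels, times,
            data.frame(condition = rep("Go", dim(data3d)[3])))
}

test_that("linked-mastoid re-reference subtracts the mastoid mean", {
  chans <- c("x", "TP9", "TP10")
  arr <- array(0, dim = c(10, 3, 1))
  arr[, 1, 1] <- 7; arr[, 2, 1] <- 5; arr[, 3, 1] <- 5
  ep <- rereference_linked_mastoids(make_epochs(arr, chans))
  expect_equal(unique(ep$data[, "x", 1]), 2)

  arr[, 1, 1] <- 10; arr[, 2, 1] <- 4; arr[, 3, 1] <- 6
  ep <- rereference_linked_mastoids(make_epochs(arr, chans))
  expect_equal(unique(ep$data[, "x", 1]), 5)  # 10 - (4+6)/2
  # mastoid-pair mean identically zero afterwards
  expect_true(all(abs(ep$data[, "TP9", ] + ep$data[, "TP10", ]) < 1e-12))

  expect_error(rereference_linked_mastoids(make_epochs(arr, c("x", "y", "z"))),
               "mastoid")
})

test_that("re-reference and baseline correction commute", {
  set.seed(42)
  cfg <- erp_gen_config()
  ep <- condition_epochs(cfg, "Go", n = 4)
  a <- baseline_correct(rereference_linked_mastoids(ep))
  b <- rereference_linked_mastoids(baseline_correct(ep))
  expect_equal(a$data, b$data, tolerance = 1e-12)
})

test_that("band-pass: passband preserved, stopband attenuated, DC removed", {
  srate <- 500
  t <- seq(0, by = 1 / srate, length.out = 1000)
  in_band <- sin(2 * pi * 10 * t)
  y <- zero_phase_bandpass(in_band, srate)
  mid <- 200:800
  expect_lt(max(abs(y[mid] - in_band[mid])) / max(abs(in_band)), 0.05)

  out_band <- sin(2 * pi * 100 * t)
  y2 <- zero_phase_bandpass(out_band, srate)
  expect_lt(max(abs(y2[mid])), 0.1)  # >= 90% reduction

  dc <- rep(50, 1000)
  y3 <- zero_phase_bandpass(dc, srate)
  expect_lt(max(abs(y3[mid])), 1)

  ep <- condition_epochs(quiet_config(), "Go", n = 2)
  expect_error(bandpass(ep, low_hz = 0, high_hz = 40), "band edges")
  expect_error(bandpass(ep, low_hz = 40, high_hz = 1), "band edges")
  expect_error(bandpass(ep, low_hz = 0.1, high_hz = 400), "band edges")
})

test_that("zero-phase filter does not shift peak latencies", {
  srate <- 500
  times <- seq(-200, 1798, by = 2)
  bump <- ifelse(abs(times - 700) <= 75,
                 8 * cos(pi * (times - 700) / 150)^2, 0)
  y <- zero_phase_bandpass(bump, srate)
  expect_equal(times[which.max(y)], 700)
})

test_that("filter agrees with signal::filtfilt away from the edges", {
  set.seed(6)
  x <- rnorm(1000)
  bw <- signal::butter(4, 40 / 250, type = "low")
  mine <- burnoutERP:::cpp_filtfilt_cols(bw$b, bw$a, matrix(x))
  ref <- signal::filtfilt(bw, x)
  mid <- 100:900
  expect_lt(max(abs(mine[mid] - ref[mid])), 1e-6)
})

test_that("rejection drops exactly the epochs over threshold", {
  cfg <- quiet_config()
  cfg$blink_rate <- 0.2
  ep <- condition_epochs(cfg, "Go", n = 100)
  set.seed(2)
  ep <- inject_artifacts(ep, cfg)
  res <- reject_artifacts(ep, threshold_uv = 80)
  expect_identical(res$log$rejected, ep$info$blink)
  expect_equal(n_epochs(res$epochs), sum(!ep$info$blink))
  expect_true(all(res$log$worst_channel[res$log$rejected] == "Fp1"))

  # flat epochs all retained
  flat <- make_epochs(array(0, c(1000, 3, 5)), c("a", "b", "Fp1"))
  expect_true(all(!reject_artifacts(flat, 80,
                                    channels = c("a", "b", "Fp1"))$log$rejected))
})

test_that("lowering the threshold never increases retained epochs", {
  set.seed(4)
  cfg <- erp_gen_config()
  ep <- condition_epochs(cfg, "Go", n = 40)
  ep <- inject_artifacts(ep, cfg)
  kept <- vapply(c(200, 120, 80, 50, 20),
                 function(th) n_epochs(reject_artifacts(ep, th)$epochs), 0L)
  expect_true(all(diff(kept) <= 0))
})

test_that("averaging: eligibility boundary at min_epochs and ON/OFF pooling", {
  cfg <- quiet_config()
  ep49 <- condition_epochs(cfg, "Go", n = 49)
  expect_false(average_conditions(ep49, min_epochs = 50)$Go$eligible)
  ep50 <- condition_epochs(cfg, "Go", n = 50)
  avg <- average_conditions(ep50, min_epochs = 50)$Go
  expect_true(avg$eligible)
  expect_equal(avg$n_epochs, 50)
  # stimulator halves are pooled into the single condition average
  tr <- test_trials(12)
  ep <- simulate_epochs(tr, cfg)
  avgs <- average_conditions(ep, min_epochs = 10)
  expect_setequal(names(avgs), c("Go", "NoGo"))
  expect_equal(avgs$Go$n_epochs, 32)
})

test_that("baseline window mean is zero after correction", {
  set.seed(3)
  cfg <- erp_gen_config()
  ep <- condition_epochs(cfg, "Go", n = 55)
  avg <- average_conditions(ep, min_epochs = 50)$Go
  bl <- colMeans(avg$data[avg$times >= -200 & avg$times <= 0, ])
  expect_true(all(abs(bl) < 1e-9))
})

test_that("averaging noise shrinks RMS by about 1/sqrt(n)", {
  set.seed(14)
  cfg <- erp_gen_config()
  cfg$components$Go[c("n2_amplitude_uv", "p3_amplitude_uv")] <- c(-1e-9, 1e-9)
  ep <- condition_epochs(cfg, "Go", n = 400)
  single_rms <- sqrt(mean(ep$data[, "CPz", ]^2))
  avg <- average_conditions(ep, min_epochs = 50)$Go
  avg_rms <- sqrt(mean(avg$data[, "CPz"]^2))
  expect_lt(avg_rms / single_rms, 2.5 / sqrt(400))
  expect_gt(avg_rms / single_rms, 0.3 / sqrt(400))
})

test_that("peak detection matches the exhaustive-scan oracle", {
  set.seed(123)
  times <- seq(-200, 1798, by = 2)
  n2_idx <- which(times >= 500 & times <= 650)
  for (k in 1:1000) {
    tr <- cumsum(rnorm(1000))  # smooth-ish random walk
    avg <- structure(list(subject_id = "s", condition = "Go",
                          channels = "CPz", times = times,
                          data = matrix(tr, ncol = 1,
                                        dimnames = list(NULL, "CPz")),
                          n_epochs = 60, eligible = TRUE),
                     class = "erp_average")
    n2 <- detect_peak(avg, "CPz", "N2")
    i_n2 <- oracle_scan(tr, n2_idx, decreasing = TRUE)
    expect_identical(n2$latency_ms, times[i_n2])
    expect_identical(n2$amplitude_uv, tr[i_n2])
    p3 <- detect_peak(avg, "CPz", "P3")
    p3_idx <- which(times >= max(600, times[i_n2] + 2) & times <= 800)
    i_p3 <- oracle_scan(tr, p3_idx, decreasing = FALSE)
    expect_identical(p3$latency_ms, times[i_p3])
    expect_identical(p3$amplitude_uv, tr[i_p3])
    expect_gt(p3$latency_ms, n2$latency_ms)
  }
})

test_that("tied extrema resolve to the earlier sample", {
  times <- seq(-200, 1798, by = 2)
  tr <- numeric(1000)
  tr[times == 700] <- 5; tr[times == 750] <- 5
  tr[times == 540] <- -3; tr[times == 600] <- -3
  avg <- structure(list(subject_id = "s", condition = "Go", channels = "CPz",
                        times = times,
                        data = matrix(tr, ncol = 1,
                                      dimnames = list(NULL, "CPz")),
                        n_epochs = 60, eligible = TRUE),
                   class = "erp_average")
  expect_equal(detect_peak(avg, "CPz", "N2")$latency_ms, 540)
  expect_equal(detect_peak(avg, "CPz", "P3")$latency_ms, 700)
})

test_that("pooling is the mean and IPL is linear in the pool", {
  lat_n2 <- c(540, 542, 538, 544, 540)
  lat_p3 <- c(728, 730, 720, 734, 726)
  chans <- c("CPz", "CP1", "CP2", "CP3", "CP4")
  meas <- rbind(
    data.frame(component = "N2", channel = chans, latency_ms = lat_n2,
               amplitude_uv = -3, stringsAsFactors = FALSE),
    data.frame(component = "P3", channel = chans, latency_ms = lat_p3,
               amplitude_uv = 8, stringsAsFactors = FALSE))
  pc <- pool_component(meas, chans, "centroparietal")
  expect_equal(pc$n2_p3_ipl_ms, mean(lat_p3 - lat_n2))
  expect_equal(pc$n2_p3_ipl_ms, mean(lat_p3) - mean(lat_n2))
  expect_equal(pc$p3_latency_ms, mean(lat_p3))
  # constant latencies across the pool give the IPL directly
  meas2 <- meas
  meas2$latency_ms <- rep(c(540, 728), each = 5)
  expect_equal(pool_component(meas2, chans)$n2_p3_ipl_ms, 188)
  expect_error(pool_component(meas[meas$channel != "CP2", ], chans),
               "missing")
})

test_that("noiseless end-to-end recovery is exact up to filter ripple", {
  for (group in c("burnout", "non_burnout")) {
    cfg <- quiet_config(group)
    ep <- condition_epochs(cfg, "Go", n = 55)
    ext <- extract_subject(ep, min_epochs = 50)
    m <- ext$measures
    cp <- m[m$pool == "centroparietal", ]
    fr <- m[m$pool == "frontal", ]
    p <- cfg$components$Go
    expect_equal(cp$p3_amplitude_uv, unname(p["p3_amplitude_uv"]),
                 tolerance = 0.02)
    expect_equal(fr$n2_amplitude_uv, unname(p["n2_amplitude_uv"]),
                 tolerance = 0.02)
    # latency within one sample of the generative latency
    expect_lte(abs(cp$p3_latency_ms - p["p3_latency_ms"]), 2)
    expect_lte(abs(fr$n2_latency_ms - p["n2_latency_ms"]), 2)
  }
})

test_that("without the filter stage noiseless recovery is bit-exact", {
  cfg <- quiet_config("burnout")
  ep <- condition_epochs(cfg, "Go", n = 55)
  ep <- rereference_linked_mastoids(ep)
  avg <- average_conditions(ep, min_epochs = 50)$Go
  m <- measure_components(avg)
  cp <- m[m$pool == "centroparietal", ]
  expect_equal(cp$p3_amplitude_uv, 9.89, tolerance = 1e-12)
  expect_equal(cp$p3_latency_ms, 728)
  expect_equal(cp$n2_p3_ipl_ms, 188)
})

test_that("stochastic recovery error stays small at default noise", {
  set.seed(55)
  cfg <- erp_gen_config("burnout")
  tr <- test_trials(20, n_test = 2)
  tr <- tr[tr$condition == "Go", ]
  amps <- ipls <- numeric(12)
  for (k in seq_along(amps)) {
    ep <- simulate_epochs(tr, cfg)
    ext <- extract_subject(ep, min_epochs = 50)
    cp <- ext$measures[ext$measures$pool == "centroparietal", ]
    amps[k] <- cp$p3_amplitude_uv
    ipls[k] <- cp$n2_p3_ipl_ms
  }
  expect_lt(median(abs(amps - 9.89)), 0.75)
  expect_lt(median(abs(ipls - 188)), 10)
})
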