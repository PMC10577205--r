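#' Construct an epoch set
#'
#' The container flowing through the preprocessing chain: a
#' samples x channels x epochs array of voltages (uV) with a time axis in
#' ms relative to trial onset and per-epoch metadata.
#'
#' @param data Numeric array `[samples, channels, epochs]`.
#' @param channels Character vector of channel names (length `dim(data)[2]`).
#' @param times Numeric vector of sample times in ms (length `dim(data)[1]`).
#' @param info Data frame with one row per epoch (condition, distractor,
#'   stimulator, blink flag, ...).
#' @param subject_id Subject identifier.
#' @param srate Sampling rate in Hz.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, channels, times, info, subject_id = "s1",
                      srate = 500) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[1] == length(times),
            dim(data)[2] == length(channels),
            dim(data)[3] == nrow(info))
  dimnames(data) <- list(NULL, channels, NULL)
  structure(list(subject_id = subject_id, channels = channels, times = times,
                 srate = srate, data = data, info = info),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> subject", x$subject_id, "-", dim(x$data)[3], "epochs x",
      length(x$channels), "channels x", length(x$times), "samples (",
      min(x$times), "..", max(x$times), "ms )\n")
  invisible(x)
}

#' @export
`[.epoch_set` <- function(x, i) {
  epoch_set(x$data[, , i, drop = FALSE], x$channels, x$times,
            x$info[i, , drop = FALSE], x$subject_id, x$srate)
}

n_epochs <- function(x) dim(x$data)[3]

# cos^2 (Hann) lobe with compact support |t - t0| <= halfwidth; peak value
# `amp` at t0. The component primitive of the waveform model.
component_lobe <- function(times, t0, halfwidth, amp) {
  d <- abs(times - t0)
  ifelse(d <= halfwidth, amp * cos(pi * d / (2 * halfwidth))^2, 0)
}

# 1/f background noise: n x m matrix, Hermitian-symmetric spectrum with
# amplitude proportional to 1/sqrt(f), random phases, globally rescaled so
# the pooled sample SD equals `sd`. Per-column SDs then vary naturally.
pink_noise <- function(n, m, sd) {
  if (sd == 0 || m == 0) return(matrix(0, n, m))
  nf <- n %/% 2
  amp <- 1 / sqrt(seq_len(nf))
  Z <- matrix(complex(real = rnorm(nf * m), imaginary = rnorm(nf * m)),
              nf, m) * amp
  spec <- matrix(0 + 0i, n, m)
  spec[2:(nf + 1), ] <- Z
  spec[n:(n - nf + 2), ] <- Conj(Z[seq_len(nf - 1), , drop = FALSE])
  x <- Re(mvfft(spec, inverse = TRUE)) / n
  x * (sd / sd(as.vector(x)))
}

# Noise-free single-epoch waveform (samples x channels) for one condition.
clean_waveform <- function(cfg, condition, times = epoch_times(cfg)) {
  p <- cfg$components[[condition]]
  n2 <- component_lobe(times, p["n2_latency_ms"], cfg$n2_halfwidth_ms,
                       p["n2_amplitude_uv"])
  p3 <- component_lobe(times, p["p3_latency_ms"], cfg$p3_halfwidth_ms,
                       p["p3_amplitude_uv"])
  outer(n2, cfg$n2_topography) + outer(p3, cfg$p3_topography)
}

#' Simulate EEG epochs for one subject
#'
#' Generates one 2,000-ms epoch per trial (-200 to +1798 ms at 500 Hz,
#' 1000 samples): the condition's noise-free waveform - topography-weighted
#' N2 and P3 lobes at the configured latencies - plus independent 1/f noise
#' per channel. Blink artifacts are added separately by
#' [inject_artifacts()]. Deterministic given the RNG state.
#'
#' @param trials Trial table (test-block trials are simulated; practice rows
#'   are dropped).
#' @param cfg An [erp_gen_config()]; validated first.
#' @param subject_id Subject identifier carried into the epoch set.
#' @return An [epoch_set()] whose `info` carries the trial metadata plus a
#'   `blink` flag (all `FALSE` here).
#' @export
simulate_epochs <- function(trials, cfg = erp_gen_config(),
                            subject_id = "s1") {
  validate_erp_config(cfg)
  if ("is_practice" %in% names(trials))
    trials <- trials[!trials$is_practice, , drop = FALSE]
  stopifnot(nrow(trials) > 0)
  times <- epoch_times(cfg)
  ns <- length(times); nc <- length(cfg$montage); ne <- nrow(trials)
  base <- lapply(c(Go = "Go", NoGo = "NoGo"), function(cond)
    clean_waveform(cfg, cond, times))
  noise <- pink_noise(ns, nc * ne, cfg$noise_sd_uv)
  dat <- array(noise, dim = c(ns, nc, ne))
  for (cond in unique(trials$condition)) {
    idx <- which(trials$condition == cond)
    dat[, , idx] <- dat[, , idx, drop = FALSE] +
      as.vector(base[[cond]])
  }
  info <- trials
  info$blink <- FALSE
  epoch_set(dat, cfg$montage, times, info, subject_id, cfg$sampling_rate)
}

#' Inject blink artifacts
#'
#' Adds a frontal-dominant blink transient (a 300-ms positive lobe of the
#' configured amplitude, centred uniformly within 0-1500 ms) to a random
#' subset of epochs selected independently with probability
#' `cfg$blink_rate`. Affected epochs are flagged in the metadata. The blink
#' amplitude must exceed 80 uV so that flagged epochs are caught by the
#' peak-to-peak rejection rule.
#'
#' @param epochs An [epoch_set()].
#' @param cfg An [erp_gen_config()].
#' @return The epoch set with blinks added and `info$blink` updated.
#' @export
inject_artifacts <- function(epochs, cfg = erp_gen_config()) {
  if (cfg$blink_amplitude_uv <= 80)
    stop("blink amplitude must exceed 80 uV")
  ne <- n_epochs(epochs)
  hit <- runif(ne) < cfg$blink_rate
  if (!any(hit)) return(epochs)
  topo <- cfg$blink_topography[epochs$channels]
  idx <- which(hit)
  t0 <- runif(length(idx), 0, 1500)
  lobes <- vapply(t0, function(tc)
    component_lobe(epochs$times, tc, cfg$blink_halfwidth_ms,
                   cfg$blink_amplitude_uv),
    numeric(length(epochs$times)))              # samples x hits
  add <- aperm(outer(lobes, topo), c(1, 3, 2))  # samples x channels x hits
  epochs$data[, , idx] <- epochs$data[, , idx, drop = FALSE] + add
  epochs$info$blink <- epochs$info$blink | hit
  epochs
}

#' Per-subject ERP parameters under the profile coupling
#'
#' Derives a subject-specific [erp_gen_config()] from the group defaults:
#' the Go-condition P3 amplitude is coupled to the subject's BBI-15 z-score
#' with within-group correlation `calib$coupling_rho` and between-subject SD
#' from the calibration; N2 amplitude and both latencies receive independent
#' between-subject jitter. Latencies are clamped to ranges compatible with
#' the peak-search windows, amplitudes floored away from zero.
#'
#' @param profile One-row data frame from [sample_profile()].
#' @param calib A [cohort_calibration()].
#' @param couple Couple the P3 amplitude to BBI-15 (default `TRUE`); with
#'   `FALSE` the amplitude still varies but independently of the profile.
#' @param subject_sd Overall scale on the between-subject spread; 0 returns
#'   the group defaults unchanged.
#' @return An `erp_gen_config` for this subject.
#' @export
subject_erp_params <- function(profile, calib = cohort_calibration(),
                               couple = TRUE, subject_sd = 1) {
  group <- profile$group[1]
  cfg <- erp_gen_config(group)
  if (subject_sd == 0) return(cfg)
  es <- calib$erp_subject
  rho <- if (couple) calib$coupling_rho else 0
  z <- rho * profile$z_bbi15[1] + sqrt(1 - rho^2) * rnorm(1)
  amp_sd <- es$p3_amp_sd[[group]] * subject_sd
  dn2a <- rnorm(1, 0, es$n2_amp_sd * subject_sd)
  dn2l <- rnorm(1, 0, es$n2_lat_sd * subject_sd)
  dp3l <- rnorm(1, 0, es$p3_lat_sd * subject_sd)
  for (cond in names(cfg$components)) {
    p <- cfg$components[[cond]]
    p["p3_amplitude_uv"] <- max(es$amp_floor, p["p3_amplitude_uv"] + amp_sd * z)
    p["n2_amplitude_uv"] <- min(-es$amp_floor, p["n2_amplitude_uv"] + dn2a)
    p["n2_latency_ms"] <- min(max(p["n2_latency_ms"] + dn2l,
                                  es$n2_lat_range[1]), es$n2_lat_range[2])
    p["p3_latency_ms"] <- min(max(p["p3_latency_ms"] + dp3l,
                                  es$p3_lat_range[1]), es$p3_lat_range[2])
    if (p["p3_latency_ms"] <= p["n2_latency_ms"] + 10)
      p["p3_latency_ms"] <- p["n2_latency_ms"] + 10
    cfg$components[[cond]] <- p
  }
  cfg
}
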