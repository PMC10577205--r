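#' Default cohort calibration
#'
#' Group-level calibration constants for the synthetic cohort: questionnaire
#' means/SDs per group, reaction-time distributions, per-type error
#' probabilities, the per-subject random-intercept SD of the error model, and
#' the between-subject ERP parameter spread with its coupling to the burnout
#' inventory score.
#'
#' Questionnaire means and SDs are those of the ERP-eligible study groups
#' (18 burnout, 17 non-burnout). Reaction times are log-normal with the
#' group median and an SD matched on the original scale. Error
#' probabilities are per-trial Bernoulli rates calibrated to the per-type
#' group medians (incorrect and missing per Go trial, commission per NoGo
#' trial); a shared per-subject intercept on the logit scale induces
#' between-subject overdispersion for the mixed logistic model to recover.
#'
#' Between-subject P3 amplitude SDs are derived from the printed group IQRs
#' (IQR/1.349 under normality). `coupling_rho` is the within-group
#' correlation between the BBI-15 z-score and the generative centroparietal
#' Go P3 amplitude; its default (0.23) is calibrated so that the mixed
#' two-group cohort attains a rank correlation of about 0.45 between BBI-15
#' and generative amplitude, the between-group separation contributing the
#' remainder.
#'
#' @return A list of class `cohort_calibration`.
#' @export
cohort_calibration <- function() {
  q <- function(mb, sb, mn, sn, lo, hi)
    list(burnout = c(mean = mb, sd = sb), non_burnout = c(mean = mn, sd = sn),
         bounds = c(lo, hi))
  structure(list(
    questionnaires = list(
      bbi15     = q(60.06, 10.34, 33.06, 8.47, 15, 90),
      bdi21     = q(15.89, 7.12, 4.12, 2.93, 0, 63),
      brief_bri = q(58.94, 11.58, 46.18, 9.86, 20, 100),
      brief_mi  = q(63.17, 9.98, 47.47, 9.86, 20, 100),
      brief_gec = q(62.06, 10.08, 46.53, 9.84, 20, 100),
      age_years = q(46.44, 8.96, 45.76, 9.71, 18, 75)
    ),
    p_female = c(burnout = 16 / 18, non_burnout = 15 / 17),
    rt = list(burnout     = c(median_ms = 358, sd_ms = 81),
              non_burnout = c(median_ms = 401, sd_ms = 107)),
    error_probs = list(
      burnout     = c(incorrect = 0.0098, miss = 0.0021, commission = 0.0117),
      non_burnout = c(incorrect = 0.0078, miss = 0.0020, commission = 0.0078)
    ),
    subject_logit_sd = 0.5,
    erp_subject = list(
      p3_amp_sd  = c(burnout = 5.69 / 1.349, non_burnout = 3.48 / 1.349),
      n2_amp_sd  = 1.0,
      p3_lat_sd  = 15,
      n2_lat_sd  = 8,
      amp_floor  = 0.5,
      n2_lat_range = c(515, 635),
      p3_lat_range = c(615, 785)
    ),
    coupling_rho = 0.23
  ), class = "cohort_calibration")
}

#' Default ERP generation configuration
#'
#' Waveform-model parameters for one group's synthetic EEG: the 10-20
#' montage, per-condition N2/P3 component latencies and amplitudes,
#' component lobe widths, channel topography weights, background-noise
#' level, and the blink-artifact model.
#'
#' Components are cos-squared (Hann) lobes: the N2 lobe spans 80 ms and the
#' P3 lobe 150 ms in total, so the two components never overlap at the
#' default latencies and a noiseless epoch's windowed extrema equal the
#' configured amplitudes. Latencies are in the trial-onset frame (the
#' Go/NoGo traffic light appears 300 ms after trial onset, so the
#' 200-350 ms post-signal N2 range maps to 500-650 ms and the P3 range to
#' 600-800 ms). Default Go-condition values place the centroparietal P3 at
#' 9.89 uV / 728 ms for the burnout group and 6.73 uV / 680 ms for the
#' non-burnout group, giving pooled N2-P3 interpeak latencies of about
#' 188 ms and 135 ms respectively; NoGo P3 amplitudes are 6.44 / 6.14 uV.
#' N2 is frontal-maximal and negative, larger for NoGo than Go; P3 is
#' centroparietal-maximal and positive, larger for Go.
#'
#' Background noise is 1/f ("pink") with SD `noise_sd_uv` (8 uV) per channel
#' per epoch. Blinks are frontal-dominant 300-ms lobes of `blink_amplitude_uv`
#' (120 uV, i.e. above the 80 uV peak-to-peak rejection threshold) injected
#' into a fraction `blink_rate` (0.1) of epochs.
#'
#' @param group `"burnout"` or `"non_burnout"`: selects the component
#'   calibration.
#' @return A list of class `erp_gen_config`.
#' @export
erp_gen_config <- function(group = c("burnout", "non_burnout")) {
  group <- match.arg(group)
  comp <- if (group == "burnout") {
    list(Go   = c(n2_latency_ms = 540, n2_amplitude_uv = -4.0,
                  p3_latency_ms = 728, p3_amplitude_uv = 9.89),
         NoGo = c(n2_latency_ms = 545, n2_amplitude_uv = -6.0,
                  p3_latency_ms = 700, p3_amplitude_uv = 6.44))
  } else {
    list(Go   = c(n2_latency_ms = 545, n2_amplitude_uv = -4.0,
                  p3_latency_ms = 680, p3_amplitude_uv = 6.73),
         NoGo = c(n2_latency_ms = 548, n2_amplitude_uv = -6.0,
                  p3_latency_ms = 696, p3_amplitude_uv = 6.14))
  }
  montage <- c("Fp1", "Fz", "F1", "F2", "F3", "F4",
               "CPz", "CP1", "CP2", "CP3", "CP4", "TP9", "TP10")
  w <- function(fp1, f, cp, tp)
    setNames(c(fp1, rep(f, 5), rep(cp, 5), rep(tp, 2)), montage)
  cfg <- list(
    group = group,
    sampling_rate = 500,
    montage = montage,
    frontal_pool = c("Fz", "F1", "F2", "F3", "F4"),
    cp_pool = c("CPz", "CP1", "CP2", "CP3", "CP4"),
    mastoids = c("TP9", "TP10"),
    components = comp,
    n2_halfwidth_ms = 40,
    p3_halfwidth_ms = 75,
    n2_topography = w(0.7, 1.0, 0.6, 0),
    p3_topography = w(0.3, 0.5, 1.0, 0),
    noise_sd_uv = 8,
    blink_rate = 0.1,
    blink_amplitude_uv = 120,
    blink_halfwidth_ms = 150,
    blink_topography = w(1.0, 0.5, 0.1, 0.05),
    epoch_start_ms = -200,
    epoch_end_ms = 1798
  )
  structure(cfg, class = "erp_gen_config")
}

#' Validate an ERP generation configuration
#'
#' Checks window compatibility: each condition's N2 latency must lie in the
#' 500-650 ms search window and P3 in 600-800 ms, with P3 later than N2, and
#' the blink amplitude must exceed the 80 uV rejection threshold.
#'
#' @param cfg An [erp_gen_config()] list.
#' @return `cfg`, invisibly; errors on violation.
#' @export
validate_erp_config <- function(cfg) {
  for (cond in names(cfg$components)) {
    p <- cfg$components[[cond]]
    if (p["n2_latency_ms"] < 500 || p["n2_latency_ms"] > 650)
      stop("N2 latency outside the 500-650 ms search window (", cond, ")")
    if (p["p3_latency_ms"] < 600 || p["p3_latency_ms"] > 800)
      stop("P3 latency outside the 600-800 ms search window (", cond, ")")
    if (p["p3_latency_ms"] <= p["n2_latency_ms"])
      stop("P3 latency must exceed N2 latency (", cond, ")")
    if (p["n2_amplitude_uv"] > 0)
      stop("N2 amplitude must be negative (", cond, ")")
  }
  if (cfg$blink_amplitude_uv <= 80)
    stop("blink amplitude must exceed the 80 uV rejection threshold")
  if (cfg$noise_sd_uv < 0) stop("noise_sd_uv must be non-negative")
  invisible(cfg)
}

#' Epoch time axis
#'
#' @param cfg An [erp_gen_config()] (only the epoch bounds and sampling rate
#'   are used).
#' @return Numeric vector of sample times in ms relative to trial onset
#'   (-200 to +1798 in 2-ms steps at the default 500 Hz: 1000 samples).
#' @export
epoch_times <- function(cfg = erp_gen_config()) {
  seq(cfg$epoch_start_ms, cfg$epoch_end_ms, by = 1000 / cfg$sampling_rate)
}
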