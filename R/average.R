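#' Average epochs by condition
#'
#' Baseline-corrects every epoch (per-channel mean over -200..0 ms) and
#' averages within condition groups. By default epochs are grouped by the
#' Go/NoGo `condition` only: the stimulator ON/OFF sub-conditions are
#' averaged together (their effect is not analysed) and distractor valences
#' are pooled, which is the level at which the minimum-epoch eligibility
#' rule is applied. Pass e.g. `by = c("condition", "distractor")` for finer
#' averages.
#'
#' A condition average built from fewer than `min_epochs` artifact-free
#' epochs is retained but marked ineligible; eligibility gates admission to
#' the group statistics.
#'
#' @param epochs An [epoch_set()] (already referenced/filtered/rejected).
#' @param by Metadata columns defining the condition key.
#' @param min_epochs Minimum contributing epochs for eligibility
#'   (default 50).
#' @param baseline Baseline window in ms.
#' @return A named list of `erp_average` objects (class
#'   `erp_average_set`), keyed by condition; each has fields `subject_id`,
#'   `condition`, `channels`, `times`, `data` (samples x channels, uV,
#'   baseline-corrected), `n_epochs`, `eligible`.
#' @export
average_conditions <- function(epochs, by = "condition", min_epochs = 50,
                               baseline = c(-200, 0)) {
  stopifnot(all(by %in% names(epochs$info)))
  epochs <- baseline_correct(epochs, baseline)
  key <- interaction(epochs$info[by], drop = TRUE, sep = "/")
  out <- lapply(levels(key), function(k) {
    idx <- which(key == k)
    avg <- rowMeans(epochs$data[, , idx, drop = FALSE], dims = 2)
    structure(list(subject_id = epochs$subject_id, condition = k,
                   channels = epochs$channels, times = epochs$times,
                   data = avg, n_epochs = length(idx),
                   eligible = length(idx) >= min_epochs),
              class = "erp_average")
  })
  names(out) <- levels(key)
  structure(out, class = "erp_average_set")
}

#' @export
print.erp_average <- function(x, ...) {
  cat("<erp_average>", x$subject_id, x$condition, "-", x$n_epochs,
      "epochs", if (!x$eligible) "(ineligible)", "\n")
  invisible(x)
}

#' Detect a component peak on one channel
#'
#' N2 is the most negative sample in the 500-650 ms window (trial-onset
#' frame); P3 is the most positive sample in 600-800 ms constrained to
#' follow the detected N2 (the window's lower edge is raised to one sample
#' past the N2 latency). Window endpoints are inclusive; ties are broken
#' toward the earlier sample. The amplitude is the waveform value at the
#' peak sample, relative to the (already subtracted) baseline.
#'
#' @param avg An `erp_average`.
#' @param channel Channel name.
#' @param component `"N2"` or `"P3"`.
#' @param n2_window,p3_window Search windows in ms.
#' @return A one-row data frame: `component`, `channel`, `latency_ms`,
#'   `amplitude_uv`.
#' @export
detect_peak <- function(avg, channel, component = c("N2", "P3"),
                        n2_window = c(500, 650), p3_window = c(600, 800)) {
  component <- match.arg(component)
  ci <- match(channel, avg$channels)
  if (is.na(ci)) stop("channel not present: ", channel)
  step <- avg$times[2] - avg$times[1]
  if (n2_window[1] < avg$times[1] || p3_window[2] > avg$times[length(avg$times)])
    stop("search window outside the epoch")
  trace <- avg$data[, ci]
  find <- function(window, fun) {
    sel <- which(avg$times >= window[1] & avg$times <= window[2])
    i <- sel[fun(trace[sel])]  # which.min/which.max return the first tie
    c(latency = avg$times[i], amplitude = trace[i])
  }
  n2 <- find(n2_window, which.min)
  if (component == "N2") {
    res <- n2
  } else {
    lo <- max(p3_window[1], n2["latency"] + step)
    if (lo > p3_window[2]) stop("P3 window empty after the N2 constraint")
    res <- find(c(lo, p3_window[2]), which.max)
  }
  data.frame(component = component, channel = channel,
             latency_ms = unname(res["latency"]),
             amplitude_uv = unname(res["amplitude"]),
             stringsAsFactors = FALSE)
}

#' Pool per-channel peak measures
#'
#' Averages amplitude and latency over the channels of a pool and computes
#' the N2-P3 interpeak latency (IPL) per channel before averaging. By
#' linearity the pooled IPL equals the pooled P3 latency minus the pooled
#' N2 latency.
#'
#' @param measures Data frame of per-channel rows as returned by
#'   [detect_peak()], containing both components for every pool channel.
#' @param channels Channel names making up the pool (all must be present).
#' @param pool Label for the pool.
#' @return One-row data frame: `pool`, `n2_amplitude_uv`, `n2_latency_ms`,
#'   `p3_amplitude_uv`, `p3_latency_ms`, `n2_p3_ipl_ms`.
#' @export
pool_component <- function(measures, channels, pool = "pool") {
  get <- function(comp) {
    m <- measures[measures$component == comp, , drop = FALSE]
    i <- match(channels, m$channel)
    if (anyNA(i))
      stop("pool channel(s) missing from measures: ",
           paste(channels[is.na(i)], collapse = ", "))
    m[i, , drop = FALSE]
  }
  n2 <- get("N2"); p3 <- get("P3")
  ipl <- mean(p3$latency_ms - n2$latency_ms)
  data.frame(pool = pool,
             n2_amplitude_uv = mean(n2$amplitude_uv),
             n2_latency_ms = mean(n2$latency_ms),
             p3_amplitude_uv = mean(p3$amplitude_uv),
             p3_latency_ms = mean(p3$latency_ms),
             n2_p3_ipl_ms = ipl,
             stringsAsFactors = FALSE)
}

#' Measure pooled N2/P3 components on an average
#'
#' Runs [detect_peak()] for both components on every channel of the frontal
#' (Fz, F1-F4) and centroparietal (CPz, CP1-CP4) pools and pools the
#' measures. Both components are measured on both pools (the centroparietal
#' N2 is needed for the centroparietal N2-P3 interpeak latency).
#'
#' @param avg An `erp_average`.
#' @param pools Named list of channel vectors.
#' @return Data frame with one row per pool: subject, condition, pooled
#'   amplitudes/latencies, IPL, and `n_epochs`.
#' @export
measure_components <- function(avg,
                               pools = list(
                                 frontal = c("Fz", "F1", "F2", "F3", "F4"),
                                 centroparietal = c("CPz", "CP1", "CP2",
                                                    "CP3", "CP4"))) {
  out <- lapply(names(pools), function(pn) {
    chans <- pools[[pn]]
    meas <- do.call(rbind, lapply(chans, function(ch)
      rbind(detect_peak(avg, ch, "N2"), detect_peak(avg, ch, "P3"))))
    cbind(data.frame(subject = avg$subject_id, condition = avg$condition,
                     stringsAsFactors = FALSE),
          pool_component(meas, chans, pn),
          data.frame(n_epochs = avg$n_epochs, eligible = avg$eligible))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Full single-subject extraction chain
#'
#' Re-reference to linked mastoids, band-pass filter, reject epochs above
#' the peak-to-peak threshold, average by condition with the minimum-epoch
#' rule, and measure pooled N2/P3 peaks and interpeak latencies.
#'
#' @param epochs Raw [epoch_set()] for one subject.
#' @param low_hz,high_hz Band edges (Hz).
#' @param threshold_uv Peak-to-peak rejection threshold (uV).
#' @param min_epochs Minimum artifact-free epochs per condition.
#' @param by Condition grouping columns for averaging.
#' @return A list with `measures` (one row per condition x pool),
#'   `rejection_log`, and `averages` (the `erp_average_set`).
#' @export
extract_subject <- function(epochs, low_hz = 0.1, high_hz = 40,
                            threshold_uv = 80, min_epochs = 50,
                            by = "condition") {
  epochs <- rereference_linked_mastoids(epochs)
  epochs <- bandpass(epochs, low_hz, high_hz)
  rej <- reject_artifacts(epochs, threshold_uv)
  if (n_epochs(rej$epochs) == 0)
    stop("all epochs rejected for subject ", epochs$subject_id)
  avgs <- average_conditions(rej$epochs, by = by, min_epochs = min_epochs)
  measures <- do.call(rbind, lapply(avgs, measure_components))
  rownames(measures) <- NULL
  list(measures = measures, rejection_log = rej$log, averages = avgs)
}
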