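#' Re-reference to linked mastoids
#'
#' Subtracts the arithmetic mean of the two mastoid channels from every
#' channel, sample-wise and epoch-wise. Afterwards the mastoid-pair mean
#' trace is identically zero. This is an affine per-channel shift and
#' commutes with baseline correction.
#'
#' @param epochs An [epoch_set()].
#' @param mastoids Names of the two mastoid channels.
#' @return The re-referenced epoch set.
#' @export
rereference_linked_mastoids <- function(epochs, mastoids = c("TP9", "TP10")) {
  miss <- setdiff(mastoids, epochs$channels)
  if (length(miss))
    stop("mastoid channel(s) missing: ", paste(miss, collapse = ", "))
  i <- match(mastoids, epochs$channels)
  ref <- (epochs$data[, i[1], , drop = FALSE] +
            epochs$data[, i[2], , drop = FALSE]) / 2
  epochs$data <- epochs$data - ref[, rep(1, length(epochs$channels)), ,
                                   drop = FALSE]
  epochs
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel of every epoch with a cascade of a 4th-order
#' Butterworth high-pass at `low_hz` and a 4th-order low-pass at `high_hz`,
#' each applied forward and backward (zero phase, so peak latencies are not
#' shifted). Constant offsets are removed exactly by the high-pass stage's
#' step-matched initial conditions. Attenuation at 0.01 Hz and at 100 Hz
#' exceeds 20 dB with the default band.
#'
#' @param epochs An [epoch_set()].
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < srate/2`.
#' @param order Butterworth order of each cascade stage.
#' @return The filtered epoch set.
#' @export
bandpass <- function(epochs, low_hz = 0.1, high_hz = 40, order = 4) {
  fn <- epochs$srate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fn))
    stop("band edges must satisfy 0 < low < high < Nyquist (", fn, " Hz)")
  d <- dim(epochs$data)
  x <- matrix(epochs$data, nrow = d[1])
  y <- zero_phase_bandpass(x, epochs$srate, low_hz, high_hz, order)
  epochs$data <- array(y, dim = d,
                       dimnames = list(NULL, epochs$channels, NULL))
  epochs
}

#' Zero-phase band-pass of a matrix of traces
#'
#' Lower-level interface used by [bandpass()]: filters each column of a
#' samples-by-traces matrix.
#'
#' @param x Numeric matrix (or vector), one trace per column.
#' @param srate Sampling rate in Hz.
#' @inheritParams bandpass
#' @return Filtered matrix of the same shape.
#' @export
zero_phase_bandpass <- function(x, srate, low_hz = 0.1, high_hz = 40,
                                order = 4) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  fn <- srate / 2
  hp <- signal::butter(order, low_hz / fn, type = "high")
  lp <- signal::butter(order, high_hz / fn, type = "low")
  # the high-pass corner is far below 1/(segment length); pad by about two
  # filter time constants so edge transients decay outside the data
  hp_pad <- min(nrow(x) - 1, ceiling(2 * srate / (2 * pi * low_hz)))
  y <- cpp_filtfilt_cols(hp$b, hp$a, x, hp_pad)
  y <- cpp_filtfilt_cols(lp$b, lp$a, y)
  if (vec) y <- drop(y)
  y
}

#' Reject epochs by peak-to-peak amplitude
#'
#' Drops every epoch in which any analysis channel's within-epoch
#' max-minus-min voltage exceeds the threshold (80 uV by default), and only
#' those. Mastoid channels are excluded from the check by default (they
#' carry the reference, not analysed signal). Lowering the threshold can
#' never increase the number of retained epochs.
#'
#' @param epochs An [epoch_set()].
#' @param threshold_uv Peak-to-peak rejection threshold (> 0).
#' @param channels Channels checked; default all non-mastoid channels.
#' @return A list with `epochs` (retained epochs) and `log`, a data frame
#'   with one row per input epoch: `epoch`, `max_p2p_uv`, `worst_channel`,
#'   `rejected`.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 80,
                             channels = setdiff(epochs$channels,
                                                c("TP9", "TP10"))) {
  stopifnot(threshold_uv > 0)
  ci <- match(channels, epochs$channels)
  if (anyNA(ci)) stop("unknown channel in 'channels'")
  sub <- epochs$data[, ci, , drop = FALSE]
  d <- dim(sub)
  p2p <- matrix(cpp_col_p2p(matrix(sub, nrow = d[1])), nrow = d[2])
  worst <- apply(p2p, 2, which.max)
  maxp <- p2p[cbind(worst, seq_along(worst))]
  rejected <- maxp > threshold_uv
  log <- data.frame(epoch = seq_along(maxp), max_p2p_uv = maxp,
                    worst_channel = channels[worst], rejected = rejected,
                    stringsAsFactors = FALSE)
  list(epochs = epochs[!rejected], log = log)
}

#' Baseline-correct epochs or averages
#'
#' Subtracts each channel's mean over the baseline window (default
#' -200..0 ms) from that channel, per epoch.
#'
#' @param epochs An [epoch_set()].
#' @param window Baseline window in ms (inclusive).
#' @return The baseline-corrected epoch set.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  sel <- epochs$times >= window[1] & epochs$times <= window[2]
  if (!any(sel)) stop("baseline window outside the epoch")
  bl <- colMeans(epochs$data[sel, , , drop = FALSE])  # channels x epochs
  ns <- length(epochs$times)
  # element (s, c, e) minus bl(c, e): recycle bl expanded along samples
  epochs$data <- epochs$data - rep(as.vector(bl), each = ns)
  epochs
}
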