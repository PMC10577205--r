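#' Write an epoch set as a BrainVision Core triplet
#'
#' Serialises the epochs as a continuous multiplexed binary recording
#' (IEEE float32, uV) with one `Stimulus` marker per epoch placed at the
#' trial-onset sample, plus the text header (`.vhdr`) and marker (`.vmrk`)
#' files. The triplet is readable by [read_brainvision()] and by
#' third-party BrainVision readers.
#'
#' @param epochs An [epoch_set()].
#' @param dir Output directory (created if needed).
#' @param basename File base name without extension.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(epochs, dir, basename = epochs$subject_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vhdr <- file.path(dir, paste0(basename, ".vhdr"))
  vmrk <- file.path(dir, paste0(basename, ".vmrk"))
  eeg  <- file.path(dir, paste0(basename, ".eeg"))
  nc <- length(epochs$channels)
  ns <- length(epochs$times)
  ne <- n_epochs(epochs)
  si_us <- 1e6 / epochs$srate

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", basename, ".eeg"),
    paste0("MarkerFile=", basename, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nc),
    paste0("SamplingInterval=", format(si_us, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nc), epochs$channels)
  )
  writeLines(hdr, vhdr, useBytes = TRUE)

  # marker position = 1-based sample index of trial onset (t = 0) within
  # the concatenated recording
  onset <- which.min(abs(epochs$times))
  pos <- (seq_len(ne) - 1L) * ns + onset
  desc <- if ("condition" %in% names(epochs$info))
    paste0("S ", epochs$info$condition) else "S  1"
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", basename, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0",
    sprintf("Mk%d=Stimulus,%s,%d,1,0", seq_len(ne) + 1L, desc, pos)
  )
  writeLines(mrk, vmrk, useBytes = TRUE)

  con <- file(eeg, "wb")
  on.exit(close(con))
  # multiplexed: channels vary fastest
  flat <- aperm(epochs$data, c(2, 1, 3))
  writeBin(as.vector(flat), con, size = 4, endian = "little")
  invisible(vhdr)
}

parse_bv_ini <- function(lines) {
  sec <- ""
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && sec != "") {
      k <- sub("=.*$", "", ln)
      v <- sub("^[^=]*=", "", ln)
      out[[sec]][[k]] <- v
    }
  }
  out
}

#' Read a BrainVision Core recording
#'
#' Parses the `.vhdr` header, the binary payload (`IEEE_FLOAT_32` or
#' `INT_16` with per-channel resolution, multiplexed orientation), and the
#' `.vmrk` markers. If `Stimulus` markers are present the recording is cut
#' into epochs of `epoch_window` around each marker; markers too close to
#' the recording edge to fit the window are dropped. Without stimulus
#' markers the continuous data are returned.
#'
#' @param vhdr_path Path to the `.vhdr` header file.
#' @param epoch_window Epoch window in ms relative to each marker
#'   (default -200..+1798, the 2,000-ms segment used throughout).
#' @param subject_id Identifier for the returned epoch set.
#' @return An [epoch_set()] if epochs were cut, otherwise a list of class
#'   `bv_recording` with `data` (samples x channels), `channels`, `srate`,
#'   `markers`.
#' @export
read_brainvision <- function(vhdr_path, epoch_window = c(-200, 1798),
                             subject_id = sub("\\.vhdr$", "",
                                              basename(vhdr_path))) {
  if (!file.exists(vhdr_path)) stop("header file not found: ", vhdr_path)
  ini <- parse_bv_ini(readLines(vhdr_path, warn = FALSE, encoding = "latin1"))
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  if (is.null(ci)) stop("not a BrainVision header: missing [Common Infos]")
  if (!is.null(ci$DataOrientation) &&
      toupper(ci$DataOrientation) != "MULTIPLEXED")
    stop("unsupported data orientation: ", ci$DataOrientation)
  if (!is.null(ci$DataFormat) && toupper(ci$DataFormat) != "BINARY")
    stop("unsupported data format: ", ci$DataFormat)
  nc <- as.integer(ci$NumberOfChannels)
  srate <- 1e6 / as.numeric(ci$SamplingInterval)
  chinfo <- ini[["Channel Infos"]]
  chans <- character(nc)
  res <- rep(1, nc)
  for (k in seq_len(nc)) {
    v <- chinfo[[paste0("Ch", k)]]
    if (is.null(v)) stop("missing channel info Ch", k)
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    chans[k] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) res[k] <- as.numeric(parts[3])
  }

  eeg_path <- file.path(dirname(vhdr_path), ci$DataFile)
  if (!file.exists(eeg_path)) stop("data file not found: ", eeg_path)
  fmt <- toupper(if (is.null(bi$BinaryFormat)) "IEEE_FLOAT_32" else
    bi$BinaryFormat)
  bytes <- file.size(eeg_path)
  word <- switch(fmt, IEEE_FLOAT_32 = 4L, INT_16 = 2L,
                 stop("unsupported binary format: ", fmt))
  n_values <- bytes / word
  if (n_values != floor(n_values) || (n_values %% nc) != 0)
    stop("truncated or corrupt data payload: ", bytes, " bytes for ",
         nc, " channels")
  ns_total <- n_values / nc
  con <- file(eeg_path, "rb")
  raw <- readBin(con, what = if (fmt == "INT_16") "integer" else "double",
                 n = n_values, size = word, endian = "little",
                 signed = TRUE)
  close(con)
  dat <- matrix(raw, nrow = nc) * res  # channels x samples
  dat <- t(dat)

  markers <- data.frame(type = character(), description = character(),
                        position = integer(), stringsAsFactors = FALSE)
  vmrk_path <- file.path(dirname(vhdr_path), ci$MarkerFile %||% "")
  if (!is.null(ci$MarkerFile) && file.exists(vmrk_path)) {
    mi <- parse_bv_ini(readLines(vmrk_path, warn = FALSE,
                                 encoding = "latin1"))[["Marker Infos"]]
    if (!is.null(mi)) {
      rows <- lapply(mi, function(v) strsplit(v, ",", fixed = TRUE)[[1]])
      markers <- data.frame(
        type = vapply(rows, `[`, "", 1),
        description = vapply(rows, `[`, "", 2),
        position = as.integer(vapply(rows, `[`, "", 3)),
        stringsAsFactors = FALSE)
    }
  }

  stim <- markers[markers$type == "Stimulus", , drop = FALSE]
  if (nrow(stim) == 0) {
    return(structure(list(data = dat, channels = chans, srate = srate,
                          markers = markers), class = "bv_recording"))
  }
  step <- 1000 / srate
  pre <- round(-epoch_window[1] / step)
  post <- round(epoch_window[2] / step)
  ns <- pre + post + 1L
  keep <- stim$position - pre >= 1 & stim$position + post <= ns_total
  stim <- stim[keep, , drop = FALSE]
  arr <- array(0, dim = c(ns, nc, nrow(stim)))
  for (i in seq_len(nrow(stim))) {
    idx <- (stim$position[i] - pre):(stim$position[i] + post)
    arr[, , i] <- dat[idx, ]
  }
  cond <- trimws(sub("^S", "", stim$description))
  info <- data.frame(condition = cond, marker_position = stim$position,
                     blink = FALSE, stringsAsFactors = FALSE)
  epoch_set(arr, chans, seq(epoch_window[1], epoch_window[2], by = step),
            info, subject_id, srate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
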