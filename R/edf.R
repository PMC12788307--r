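#' Write a recording to an EDF file
#'
#' Minimal European Data Format (EDF) writer: 16-bit samples, one data
#' record per second, per-channel physical scaling chosen symmetrically
#' from the data range. If the recording does not span a whole number of
#' seconds the final record is zero-padded; the true sample count is
#' stored in the header's reserved field and honoured by [read_edf()].
#'
#' @param rec an `eeg_recording` (amplitudes in microvolts)
#' @param path output file path
#' @param patient_id,recording_id free-text header fields (<= 80 chars)
#' @return `path`, invisibly
#' @seealso [read_edf()]
#' @export
write_edf <- function(rec, path, patient_id = "X", recording_id = "X") {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  sr <- rec$sampling_rate
  if (abs(sr - round(sr)) > 1e-9)
    stop("EDF writer requires an integer sampling rate; got ", sr)
  sr <- as.integer(round(sr))
  n <- ncol(rec$data)
  n_rec <- as.integer(ceiling(n / sr))

  pad <- function(x, width) {
    x <- substr(as.character(x), 1L, width)
    formatC(x, width = width, flag = "-")
  }
  phys_max <- apply(abs(rec$data), 1L, max)
  phys_max <- ifelse(phys_max > 0, phys_max, 1)
  phys_max <- signif(phys_max * 1.0000001, 7)  # keep all samples inside range

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad(patient_id, 80), pad(recording_id, 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256L * (1L + ns), 8),
    pad(sprintf("NS=%d", n), 44),
    pad(n_rec, 8), pad("1", 8), pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) writeChar(paste0(vapply(vals, pad, "", width = width),
                                                  collapse = ""), con, eos = NULL)
  field(rec$channel_names, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(formatC(-phys_max, format = "g", digits = 6), 8)
  field(formatC(phys_max, format = "g", digits = 6), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)
  field(rep(sr, ns), 8)
  field(rep("", ns), 32)

  # parse back the (7-char-rounded) physical range for exact inverse scaling
  pm <- as.numeric(formatC(phys_max, format = "g", digits = 6))
  scale <- 32767 / pm
  x <- rec$data
  if (n_rec * sr > n)
    x <- cbind(x, matrix(0, ns, n_rec * sr - n))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * sr + 1L):(r * sr)
    dig <- round(x[, idx, drop = FALSE] * scale)
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Supports the plain 16-bit EDF layout produced by this package (equal
#' sampling rate across channels, one-second records). Digital values are
#' rescaled to physical microvolts using each channel's header range.
#'
#' @param path EDF file path
#' @return an `eeg_recording`
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                       # version
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8))
  phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8))
  dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-channel sampling rates are not supported")
  sr <- spr[1L] / rec_dur
  out <- matrix(0, ns, n_rec * spr[1L])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  off <- phys_min - gain * dig_min
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr[1L], size = 2L,
                     signed = TRUE, endian = "little")
    idx <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    out[, idx] <- matrix(block, nrow = ns, byrow = TRUE) * gain + off
  }
  if (grepl("^NS=\\d+$", reserved)) {
    n_true <- as.integer(sub("^NS=", "", reserved))
    out <- out[, seq_len(n_true), drop = FALSE]
  }
  eeg_recording(out, sr, labels)
}
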