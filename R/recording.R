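#' Construct an EEG recording object
#'
#' The basic container for one continuous multichannel recording: a
#' channels x samples matrix in microvolts, the sampling rate, channel
#' names, and optional annotations and quality-control state.
#'
#' @param data numeric matrix, channels x samples, in microvolts
#' @param sampling_rate sampling rate in Hz
#' @param channel_names character vector, one unique name per row of `data`
#' @param annotations data.frame with columns `onset`, `duration`
#'   (seconds) and `label`, or NULL
#' @param bad_channels character vector of channels flagged bad
#' @param bad_segments data.frame with columns `onset`, `duration`
#'   (seconds), or NULL
#' @return object of class `eeg_recording`
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 500), 2), 250, c("Cz", "Pz"))
#' recording_duration(rec)
#' @export
eeg_recording <- function(data, sampling_rate, channel_names,
                          annotations = NULL, bad_channels = character(),
                          bad_segments = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1L || ncol(data) < 1L)
    stop("`data` must be a non-empty numeric channels x samples matrix")
  if (length(channel_names) != nrow(data))
    stop("length(channel_names) must equal nrow(data): ",
         length(channel_names), " vs ", nrow(data))
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("`sampling_rate` must be a positive scalar (Hz)")
  rownames(data) <- channel_names
  dur <- ncol(data) / sampling_rate
  annotations <- .check_intervals(annotations, dur, "annotations", need_label = TRUE)
  bad_segments <- .check_intervals(bad_segments, dur, "bad_segments")
  structure(
    list(data = data, sampling_rate = sampling_rate,
         channel_names = as.character(channel_names),
         annotations = annotations,
         bad_channels = as.character(bad_channels),
         bad_segments = bad_segments),
    class = "eeg_recording"
  )
}

.check_intervals <- function(x, dur, what, need_label = FALSE) {
  cols <- c("onset", "duration", if (need_label) "label")
  if (is.null(x)) {
    x <- as.data.frame(stats::setNames(
      c(list(numeric(0), numeric(0)), if (need_label) list(character(0))), cols))
    return(x)
  }
  if (!all(cols %in% names(x)))
    stop(what, " must have columns: ", paste(cols, collapse = ", "))
  if (any(x$onset < 0) || any(x$onset + x$duration > dur + 1e-9))
    stop(what, " must lie within [0, ", signif(dur, 6), "] s")
  x[, cols, drop = FALSE]
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate, recording_duration(x)))
  if (length(x$bad_channels))
    cat("  bad channels:", paste(x$bad_channels, collapse = ", "), "\n")
  if (nrow(x$bad_segments))
    cat(sprintf("  bad segments: %d (%.2f s total)\n",
                nrow(x$bad_segments), sum(x$bad_segments$duration)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$sampling_rate

#' Crop a resting-state recording to its first two minutes
#'
#' Analysis of the resting block uses only the first 120 s so that every
#' subject contributes the same amount of resting data. Recordings shorter
#' than 120 s are returned unchanged with a warning.
#'
#' @param rec an `eeg_recording`
#' @param seconds window length to keep (default 120)
#' @return cropped `eeg_recording`
#' @export
crop_resting <- function(rec, seconds = 120) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_keep <- round(seconds * rec$sampling_rate)
  if (ncol(rec$data) < n_keep) {
    warning(sprintf("recording is %.1f s < %g s; using full length",
                    recording_duration(rec), seconds))
    return(rec)
  }
  clip <- function(df) {
    df <- df[df$onset < seconds, , drop = FALSE]
    df$duration <- pmin(df$duration, seconds - df$onset)
    df
  }
  eeg_recording(rec$data[, seq_len(n_keep), drop = FALSE], rec$sampling_rate,
                rec$channel_names, annotations = clip(rec$annotations),
                bad_channels = rec$bad_channels,
                bad_segments = clip(rec$bad_segments))
}
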