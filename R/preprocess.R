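#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero-phase, so oscillatory phase relationships used by coherence are
#' not distorted), with odd-reflection padding at the edges to suppress
#' filter transients.
#'
#' @param rec an `eeg_recording`
#' @param low,high band edges in Hz (defaults 0.5 and 45)
#' @return filtered `eeg_recording` of identical shape
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 45) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(0 < low && low < high)) stop("need 0 < low < high")
  if (high >= nyq)
    stop("`high` (", high, " Hz) must be below the Nyquist frequency (", nyq, " Hz)")
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  # pad long enough for the slow corner's transient to settle
  npad <- max(108L, round(rec$sampling_rate / low))
  out <- rec
  out$data <- t(apply(rec$data, 1L, .filtfilt_reflect, b = bf$b, a = bf$a,
                      npad = npad))
  rownames(out$data) <- rec$channel_names
  out
}

# forward-backward IIR on the de-meaned signal with odd reflection padding
.filtfilt_reflect <- function(x, b, a, npad = 108L) {
  x <- x - mean(x)
  n <- length(x)
  np <- min(npad, n - 1L)
  ext <- c(2 * x[1] - x[(np + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - np)])
  y <- as.numeric(signal::filter(b, a, ext))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(np + 1L):(np + n)]
}

#' Detect flatlined bad channels
#'
#' A channel is bad when strictly more than `fraction` of its samples are
#' near zero (|x| < `amp` microvolts) -- the prolonged-flatline rule.
#'
#' @param rec an `eeg_recording`
#' @param fraction flagging threshold on the near-zero sample fraction
#'   (strict inequality; default 0.60)
#' @param amp near-zero amplitude bound in microvolts (default 1e-10)
#' @return character vector of bad channel names
#' @export
detect_bad_channels <- function(rec, fraction = 0.60, amp = 1e-10) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(fraction > 0 && fraction < 1)) stop("`fraction` must be in (0, 1)")
  if (ncol(rec$data) == 0L) stop("empty recording")
  frac_flat <- rowMeans(abs(rec$data) < amp)
  rec$channel_names[frac_flat > fraction]
}

# maximal runs of near-zero samples in one channel, as sample index ranges
.flat_runs <- function(x, amp, min_samples) {
  r <- rle(abs(x) < amp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_samples
  cbind(start = starts[keep], end = ends[keep])
}

#' Detect transient flatline segments
#'
#' Finds maximal contiguous runs of near-zero samples (|x| < `amp`)
#' lasting at least `min_run` seconds in any channel; runs that overlap
#' across channels are merged into single intervals.
#'
#' @param rec an `eeg_recording`
#' @param amp near-zero amplitude bound, microvolts
#' @param min_run minimum run length, seconds
#' @return data.frame with columns `onset` and `duration` (seconds),
#'   possibly empty
#' @export
detect_bad_segments <- function(rec, amp = 1e-10, min_run = 0.2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (min_run <= 0) stop("`min_run` must be > 0")
  fs <- rec$sampling_rate
  min_samples <- max(1L, ceiling(min_run * fs))
  runs <- do.call(rbind, lapply(seq_len(nrow(rec$data)), function(ch)
    .flat_runs(rec$data[ch, ], amp, min_samples)))
  if (is.null(runs) || nrow(runs) == 0L)
    return(data.frame(onset = numeric(0), duration = numeric(0)))
  iv <- cbind((runs[, "start"] - 1L) / fs, runs[, "end"] / fs)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(merged)
    if (iv[i, 1] <= merged[last, 2]) {
      merged[last, 2] <- max(merged[last, 2], iv[i, 2])
    } else {
      merged <- rbind(merged, iv[i, , drop = FALSE])
    }
  }
  data.frame(onset = merged[, 1], duration = merged[, 2] - merged[, 1])
}

# Perrin-style spherical spline machinery -----------------------------------

# g(x) = (1/4pi) sum_{l=1}^{L} (2l+1) / (l^m (l+1)^m) P_l(x)
.spline_g <- function(x, m = 4, nterms = 50) {
  d <- dim(x)
  x <- pmin(1, pmax(-1, as.numeric(x)))   # pmin/pmax drop dims; restored below
  p_prev <- rep(1, length(x))  # P_0
  p_cur <- x                   # P_1
  acc <- (2 * 1 + 1) / (1^m * 2^m) * p_cur
  for (l in 2:nterms) {
    p_next <- ((2 * l - 1) * x * p_cur - (l - 1) * p_prev) / l
    acc <- acc + (2 * l + 1) / (l^m * (l + 1)^m) * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  out <- acc / (4 * pi)
  dim(out) <- d
  out
}

#' Reconstruct bad channels by spherical spline interpolation
#'
#' Fits, at every time point, a spherical spline (stiffness order m = 4,
#' Legendre series truncated at 50 terms, ridge regularization 1e-5) to
#' the good-channel potentials on the unit-sphere montage and evaluates it
#' at the bad electrode positions. Good channels are returned untouched.
#'
#' @param rec an `eeg_recording`
#' @param bad channel names to reconstruct (default: `rec$bad_channels`)
#' @param montage an `eeg_montage` covering all channels of `rec`
#' @param m spline stiffness order
#' @param nterms Legendre series truncation
#' @param reg ridge term added to the spline system
#' @return `eeg_recording` with bad channels replaced
#' @export
interpolate_channels <- function(rec, bad = rec$bad_channels,
                                 montage = standard_montage_64(),
                                 m = 4, nterms = 50, reg = 1e-5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!length(bad)) return(rec)
  if (!all(bad %in% rec$channel_names))
    stop("bad channels not in recording: ",
         paste(setdiff(bad, rec$channel_names), collapse = ", "))
  mon <- montage_subset(montage, rec$channel_names)
  good <- setdiff(rec$channel_names, bad)
  if (length(good) < 4L)
    stop("spherical spline interpolation needs at least 4 good channels; have ",
         length(good))
  pg <- mon$pos3d[match(good, mon$channels), , drop = FALSE]
  pb <- mon$pos3d[match(bad, mon$channels), , drop = FALSE]
  G <- .spline_g(tcrossprod(pg), m, nterms)
  Gb <- .spline_g(tcrossprod(pb, pg), m, nterms)
  ng <- length(good)
  A <- rbind(cbind(G + diag(reg, ng), rep(1, ng)), c(rep(1, ng), 0))
  V <- rbind(rec$data[good, , drop = FALSE], 0)
  sol <- solve(A, V)                       # (ng + 1) x T: coefficients + c0
  est <- Gb %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1L, ], nrow(pb), ncol(rec$data), byrow = TRUE)
  out <- rec
  out$data[match(bad, rec$channel_names), ] <- est
  out
}

#' Remove artifact components by template correlation
#'
#' Pluggable stand-in for classifier-based independent-component
#' rejection: the recording is decomposed with a deterministic linear
#' unmixing (principal components via SVD), components whose absolute
#' correlation with the supplied reference time course exceeds
#' `threshold` are zeroed, and the data are re-mixed. The removed-artifact
#' duration fraction (time the removed signal is active relative to the
#' recording length) is reported for QC.
#'
#' A different decomposition or classifier can be substituted through
#' `decompose`: a function(data matrix) returning list(sources, mixing)
#' with data = mixing %*% sources.
#'
#' @param rec an `eeg_recording`
#' @param reference numeric artifact template, same length as the
#'   recording
#' @param threshold absolute-correlation cutoff in (0, 1]
#' @param decompose optional alternative decomposition function
#' @return list: `recording` (cleaned), `removed_fraction` (in [0, 1]),
#'   `n_removed` components
#' @export
remove_artifact_components <- function(rec, reference, threshold = 0.8,
                                       decompose = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(reference) != ncol(rec$data))
    stop("`reference` must have one sample per recording sample")
  if (!(threshold > 0 && threshold <= 1))
    stop("`threshold` must be in (0, 1]")
  dec <- tryCatch({
    if (is.null(decompose)) {
      ctr <- rec$data - rowMeans(rec$data)
      sv <- svd(ctr)
      list(sources = t(sv$v) * sv$d, mixing = sv$u,
           means = rowMeans(rec$data))
    } else {
      c(decompose(rec$data), list(means = 0))
    }
  }, error = function(e) {
    warning("decomposition failed (", conditionMessage(e),
            "); no components removed")
    NULL
  })
  if (is.null(dec))
    return(list(recording = rec, removed_fraction = 0, n_removed = 0L))
  src_sd <- apply(dec$sources, 1L, stats::sd)
  usable <- src_sd > 0 & stats::sd(reference) > 0
  cors <- rep(0, nrow(dec$sources))
  cors[usable] <- abs(apply(dec$sources[usable, , drop = FALSE], 1L,
                            stats::cor, y = reference))
  drop_idx <- which(cors > threshold)
  if (!length(drop_idx))
    return(list(recording = rec, removed_fraction = 0, n_removed = 0L))
  removed <- dec$mixing[, drop_idx, drop = FALSE] %*%
    dec$sources[drop_idx, , drop = FALSE]
  out <- rec
  out$data <- rec$data - removed
  # active time of the removed signal: samples above 10% of its peak envelope
  env <- sqrt(colMeans(removed^2))
  frac <- mean(env > 0.1 * max(env))
  list(recording = out, removed_fraction = frac, n_removed = length(drop_idx))
}

#' Per-recording preprocessing quality report
#'
#' Computes the three QC percentages: bad channels / total channels;
#' per-channel flatline time summed over channels / (channels x recording
#' duration); removed-artifact duration / recording duration.
#'
#' @param rec the original (pre-cleaning) `eeg_recording`
#' @param bad_channels character vector of flagged channels
#' @param artifact_fraction removed-artifact duration fraction (0-1)
#' @param amp,min_run flatline detection parameters (as in
#'   [detect_bad_segments()])
#' @return one-row data.frame: pct_bad_channels, pct_bad_segments,
#'   pct_artifacts_removed
#' @export
preprocess_report <- function(rec, bad_channels = character(),
                              artifact_fraction = 0,
                              amp = 1e-10, min_run = 0.2) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_ch <- nrow(rec$data)
  n <- ncol(rec$data)
  min_samples <- max(1L, ceiling(min_run * rec$sampling_rate))
  good <- setdiff(rec$channel_names, bad_channels)
  flat_samples <- sum(vapply(good, function(ch) {
    runs <- .flat_runs(rec$data[ch, ], amp, min_samples)
    if (nrow(runs)) sum(runs[, "end"] - runs[, "start"] + 1L) else 0L
  }, 0L))
  data.frame(
    pct_bad_channels = 100 * length(bad_channels) / n_ch,
    pct_bad_segments = 100 * flat_samples / (n_ch * n),
    pct_artifacts_removed = 100 * artifact_fraction
  )
}

#' Cohort-level QC summary
#'
#' Aggregates per-subject QC reports to cohort mean and SD of each
#' percentage, invariant to subject and channel ordering.
#'
#' @param reports data.frame of rows from [preprocess_report()] (or a
#'   list of such rows)
#' @return list with `per_subject` (data.frame) and `summary`
#'   (data.frame: metric, mean, sd)
#' @export
qc_summary <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports))
    reports <- do.call(rbind, reports)
  metrics <- c("pct_bad_channels", "pct_bad_segments", "pct_artifacts_removed")
  stopifnot(all(metrics %in% names(reports)))
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(reports[[m]]), 0),
    sd = vapply(metrics, function(m) stats::sd(reports[[m]]), 0),
    row.names = NULL
  )
  list(per_subject = reports, summary = summary)
}

#' Full preprocessing chain for one recording
#'
#' Stage order: band-pass filter, flatline bad-channel detection,
#' spherical-spline reconstruction, flatline bad-segment detection
#' (segments are retained as exclusion intervals, never concatenated
#' across a gap), then optional template-based artifact removal.
#'
#' @param rec an `eeg_recording`
#' @param montage an `eeg_montage`
#' @param low,high filter band (Hz)
#' @param flat_fraction,flat_amp,min_run flatline rules
#' @param artifact_reference optional template for
#'   [remove_artifact_components()] (NULL skips the stage)
#' @param artifact_threshold correlation cutoff
#' @return list: `recording` (cleaned, with `bad_channels` and
#'   `bad_segments` populated) and `report` (from [preprocess_report()])
#' @export
preprocess_recording <- function(rec, montage = standard_montage_64(),
                                 low = 0.5, high = 45,
                                 flat_fraction = 0.60, flat_amp = 1e-10,
                                 min_run = 0.2,
                                 artifact_reference = NULL,
                                 artifact_threshold = 0.8) {
  bad <- detect_bad_channels(rec, flat_fraction, flat_amp)
  filt <- bandpass_filter(rec, low, high)
  # filtering smears flatlines; re-impose exact zeros on detected channels
  filt$data[match(bad, filt$channel_names), ] <- 0
  if (length(bad)) filt <- interpolate_channels(filt, bad, montage)
  segs_rec <- rec
  segs_rec$data[match(bad, rec$channel_names), ] <- NA_real_
  segs_rec$data[is.na(segs_rec$data)] <- 1  # interpolated channels can't flag segments
  segs <- detect_bad_segments(segs_rec, flat_amp, min_run)
  art_frac <- 0
  if (!is.null(artifact_reference)) {
    cleaned <- remove_artifact_components(filt, artifact_reference,
                                          artifact_threshold)
    filt <- cleaned$recording
    art_frac <- cleaned$removed_fraction
  }
  filt$bad_channels <- bad
  filt$bad_segments <- segs
  report <- preprocess_report(rec, bad, art_frac, flat_amp, min_run)
  list(recording = filt, report = report)
}
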