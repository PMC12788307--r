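#' Welch-averaged cross-spectral matrices
#'
#' Hermitian cross-spectral density matrix S(f) per frequency bin, using
#' exactly the same segmentation, taper and scaling as [welch_psd()], so
#' diag(S(f)) reproduces the PSD.
#'
#' @param rec an `eeg_recording`
#' @param window,overlap Welch parameters (as in [welch_psd()])
#' @param fmax highest frequency bin to retain (default 45 Hz; the full
#'   grid is rarely needed and the matrices are dense)
#' @return object of class `eeg_csd`: list with `frequencies`, `S`
#'   (complex array channels x channels x bins), `channel_names`,
#'   `n_segments`
#' @export
cross_spectra <- function(rec, window = 2, overlap = 0.5, fmax = 45) {
  segs <- .welch_fft_segments(rec, window, overlap)
  keep <- which(segs$freq <= fmax + 1e-9)
  n_ch <- nrow(rec$data)
  K <- length(segs$fft)
  # bins x channels x segments
  arr <- array(0i, c(length(keep), n_ch, K))
  for (k in seq_len(K)) arr[, , k] <- segs$fft[[k]][keep, , drop = FALSE]
  scale <- 2 / (rec$sampling_rate * sum(segs$taper^2))
  S <- array(0i, c(n_ch, n_ch, length(keep)),
             dimnames = list(rec$channel_names, rec$channel_names, NULL))
  for (b in seq_along(keep)) {
    M <- t(arr[b, , , drop = TRUE])            # segments x channels
    if (K == 1L) M <- matrix(arr[b, , 1L], nrow = 1L)
    Sb <- crossprod(Conj(M), M) / K * scale    # sum_k conj(X_i) X_j ... Hermitian
    S[, , b] <- Conj(Sb)                       # S_ij = E[X_i conj(X_j)]
  }
  if (segs$freq[keep[1]] == 0) S[, , 1L] <- S[, , 1L] / 2
  structure(list(frequencies = segs$freq[keep], S = S,
                 channel_names = rec$channel_names, n_segments = K),
            class = "eeg_csd")
}

#' @export
print.eeg_csd <- function(x, ...) {
  cat(sprintf("<eeg_csd> %d ch, %d bins (%.2f-%.1f Hz), %d segments\n",
              length(x$channel_names), length(x$frequencies),
              min(x$frequencies), max(x$frequencies), x$n_segments))
  invisible(x)
}

#' Imaginary part of coherency
#'
#' For every channel pair and frequency bin, the coherency
#' C_xy(f) = S_xy(f) / sqrt(S_xx(f) S_yy(f)); the band-level connectivity
#' value is the mean over the band's bins of |Im C_xy(f)| (absolute value
#' by default, preventing sign cancellation across bins; set
#' `signed = TRUE` for the signed average). The imaginary part discards
#' zero-lag coupling, making the measure robust to volume conduction.
#'
#' @param csd an `eeg_csd`
#' @param band one row of [band_definitions()] (or any list with `band`,
#'   `f_low`, `f_high`)
#' @param signed average Im C itself rather than |Im C|
#' @return symmetric channels x channels matrix with zero diagonal,
#'   entries in [0, 1] (class `conn_matrix`, with attribute `band`)
#' @export
imaginary_coherence <- function(csd, band, signed = FALSE) {
  stopifnot(inherits(csd, "eeg_csd"))
  sel <- which(csd$frequencies >= band$f_low & csd$frequencies < band$f_high)
  if (!length(sel))
    stop(sprintf("no frequency bins in band [%g, %g) Hz", band$f_low, band$f_high))
  n_ch <- length(csd$channel_names)
  acc <- matrix(0, n_ch, n_ch)
  warned <- FALSE
  for (b in sel) {
    Sb <- csd$S[, , b]
    auto <- Re(diag(Sb))
    denom <- sqrt(outer(auto, auto))
    bad <- denom <= 0
    if (any(bad[upper.tri(bad)]) && !warned) {
      warning("zero auto-spectrum in band; affected entries set to 0")
      warned <- TRUE
    }
    denom[bad] <- Inf
    C <- Im(Sb) / denom
    acc <- acc + if (signed) C else abs(C)
  }
  out <- acc / length(sel)
  out <- (out + t(out)) / 2
  diag(out) <- 0
  dimnames(out) <- list(csd$channel_names, csd$channel_names)
  structure(out, class = c("conn_matrix", class(out)), band = band$band)
}

#' Band connectivity matrices for a whole cohort
#'
#' Computes the imaginary-coherence matrix for every subject, task and
#' band.
#'
#' @param cohort an `eeg_cohort`
#' @param bands band table (default all five canonical bands)
#' @param window,overlap Welch parameters
#' @return nested list `[[subject_id]][[task]][[band]]` of connectivity
#'   matrices
#' @export
cohort_connectivity <- function(cohort, bands = band_definitions(),
                                window = 2, overlap = 0.5) {
  out <- list()
  for (s in cohort$subjects) {
    per_task <- list()
    for (task in names(s$recordings)) {
      csd <- cross_spectra(s$recordings[[task]], window, overlap)
      per_task[[task]] <- lapply(seq_len(nrow(bands)), function(b)
        imaginary_coherence(csd, bands[b, ]))
      names(per_task[[task]]) <- bands$band
    }
    out[[s$subject_id]] <- per_task
  }
  out
}

#' Write a connectivity matrix as a delimited table
#'
#' Square comma-separated table with channel names as header row and
#' first column.
#'
#' @param w connectivity matrix
#' @param path output path
#' @export
write_connectivity <- function(w, path) {
  utils::write.csv(as.data.frame(unclass(w)), path, row.names = TRUE)
  invisible(path)
}
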