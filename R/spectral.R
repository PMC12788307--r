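#' Welch power spectral density
#'
#' Averaged modified periodogram with a Hann taper. The recording is
#' first cut at its `bad_segments` (excluded intervals never contribute
#' and data are never concatenated across a gap); every remaining
#' continuous chunk is segmented with the requested window and overlap
#' and all segments are averaged jointly.
#'
#' @param rec an `eeg_recording`
#' @param window segment length in seconds (default 2, i.e. 0.5 Hz
#'   resolution)
#' @param overlap fractional overlap between segments (default 0.5)
#' @return object of class `eeg_psd`: list with `frequencies` (Hz),
#'   `power` (channels x bins, microvolt^2/Hz, one-sided), `n_segments`,
#'   and the estimation parameters
#' @export
welch_psd <- function(rec, window = 2, overlap = 0.5) {
  segs <- .welch_fft_segments(rec, window, overlap)
  ps <- Reduce(`+`, lapply(segs$fft, function(X) abs(X)^2)) / length(segs$fft)
  scale <- 2 / (rec$sampling_rate * sum(segs$taper^2))
  power <- t(ps) * scale
  power[, 1L] <- power[, 1L] / 2                      # DC not doubled
  if (segs$n_win %% 2L == 0L)
    power[, ncol(power)] <- power[, ncol(power)] / 2  # Nyquist not doubled
  structure(list(frequencies = segs$freq, power = power,
                 channel_names = rec$channel_names,
                 n_segments = length(segs$fft),
                 window = window, overlap = overlap, taper = "hann"),
            class = "eeg_psd")
}

#' @export
print.eeg_psd <- function(x, ...) {
  cat(sprintf("<eeg_psd> %d ch, %d bins (0-%.1f Hz), %d segments, %gs %s window\n",
              nrow(x$power), length(x$frequencies), max(x$frequencies),
              x$n_segments, x$window, x$taper))
  invisible(x)
}

# Shared Welch segmentation: returns per-segment FFT matrices
# (bins x channels) so PSD and cross-spectra use identical estimates.
.welch_fft_segments <- function(rec, window, overlap) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(overlap >= 0 && overlap < 1)) stop("`overlap` must be in [0, 1)")
  fs <- rec$sampling_rate
  n_win <- round(window * fs)
  if (n_win < 4L) stop("window too short")
  step <- max(1L, round(n_win * (1 - overlap)))
  chunks <- .good_chunks(rec)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_win) / (n_win + 1))  # Hann
  nf <- floor(n_win / 2) + 1L
  ffts <- list()
  short <- 0L
  for (ck in chunks) {
    len <- ck[2] - ck[1] + 1L
    if (len < n_win) { short <- short + 1L; next }
    starts <- seq(ck[1], ck[2] - n_win + 1L, by = step)
    for (s0 in starts) {
      seg <- t(rec$data[, s0:(s0 + n_win - 1L), drop = FALSE]) * taper
      ffts[[length(ffts) + 1L]] <- stats::mvfft(seg)[seq_len(nf), , drop = FALSE]
    }
  }
  if (short > 0L)
    warning(short, " chunk(s) shorter than the window were skipped")
  if (!length(ffts))
    stop("no chunk is long enough for the requested window")
  list(fft = ffts, taper = taper, n_win = n_win,
       freq = (seq_len(nf) - 1L) * fs / n_win)
}

# continuous sample-index ranges between excluded bad segments
.good_chunks <- function(rec) {
  n <- ncol(rec$data)
  bs <- rec$bad_segments
  if (is.null(bs) || nrow(bs) == 0L) return(list(c(1L, n)))
  fs <- rec$sampling_rate
  bs <- bs[order(bs$onset), , drop = FALSE]
  chunks <- list()
  cur <- 1L
  for (i in seq_len(nrow(bs))) {
    i0 <- floor(bs$onset[i] * fs) + 1L
    i1 <- min(n, ceiling((bs$onset[i] + bs$duration[i]) * fs))
    if (i0 > cur) chunks[[length(chunks) + 1L]] <- c(cur, i0 - 1L)
    cur <- max(cur, i1 + 1L)
  }
  if (cur <= n) chunks[[length(chunks) + 1L]] <- c(cur, n)
  chunks
}

# trapezoid integral of each channel's PSD over [lo, hi], with linear
# interpolation at the limits when they fall between grid points
.band_integral <- function(psd, lo, hi) {
  f <- psd$frequencies
  interp_at <- function(f0)
    apply(psd$power, 1L, function(p) stats::approx(f, p, xout = f0, rule = 2)$y)
  inside <- which(f > lo & f < hi)
  fgrid <- c(lo, f[inside], hi)
  pm <- rbind(interp_at(lo), t(psd$power[, inside, drop = FALSE]), interp_at(hi))
  dn <- diff(fgrid)
  colSums((pm[-nrow(pm), , drop = FALSE] + pm[-1L, , drop = FALSE]) / 2 * dn)
}

#' Relative band power
#'
#' For each channel, the fraction of total 0.5-45 Hz spectral power
#' contained in each canonical band: the trapezoid integral of the PSD
#' over the band divided by the integral over the whole 0.5-45 Hz range.
#' Shared band edges receive half weight on each side, so the five
#' fractions sum to exactly 1.
#'
#' @param psd an `eeg_psd` whose grid covers [0.5, 45] Hz
#' @param bands band table as from [band_definitions()]
#' @return channels x bands matrix of fractions; a channel with zero
#'   total power yields NA in every band (with a warning)
#' @export
relative_power <- function(psd, bands = band_definitions()) {
  stopifnot(inherits(psd, "eeg_psd"))
  lo <- min(bands$f_low); hi <- max(bands$f_high)
  if (min(psd$frequencies) > lo || max(psd$frequencies) < hi)
    stop(sprintf("PSD grid must cover [%g, %g] Hz", lo, hi))
  bp <- vapply(seq_len(nrow(bands)), function(b)
    .band_integral(psd, bands$f_low[b], bands$f_high[b]),
    numeric(nrow(psd$power)))
  bp <- matrix(bp, nrow = nrow(psd$power),
               dimnames = list(psd$channel_names, bands$band))
  total <- rowSums(bp)
  zero <- total <= 0
  if (any(zero)) {
    warning("zero total power in channel(s): ",
            paste(psd$channel_names[zero], collapse = ", "))
    bp[zero, ] <- NA_real_
    total[zero] <- 1
  }
  bp / total
}

#' Per-subject relative band power table for a cohort
#'
#' Runs [welch_psd()] and [relative_power()] on every recording of every
#' subject and returns a long table, aggregated to scalp lobes.
#'
#' @param cohort an `eeg_cohort` (recordings may be raw or preprocessed)
#' @param window,overlap Welch parameters
#' @param level "region" (default) or "channel"
#' @param mapping optional channel-to-lobe override (see
#'   [channel_lobes()])
#' @param average_spectra if TRUE, average member-channel PSDs before
#'   computing relative power instead of averaging per-channel fractions
#' @return data.frame: subject_id, group, age, task, region-or-channel,
#'   band, rp
#' @export
cohort_band_power <- function(cohort, window = 2, overlap = 0.5,
                              level = c("region", "channel"),
                              mapping = NULL, average_spectra = FALSE) {
  level <- match.arg(level)
  rows <- list()
  for (s in cohort$subjects) {
    for (task in names(s$recordings)) {
      rec <- s$recordings[[task]]
      psd <- welch_psd(rec, window, overlap)
      if (level == "channel") {
        rp <- relative_power(psd)
        df <- expand.grid(channel = rownames(rp), band = colnames(rp),
                          stringsAsFactors = FALSE)
        df$rp <- as.numeric(rp)
      } else if (average_spectra) {
        lob <- channel_lobes(rec$channel_names, mapping)
        sub <- do.call(rbind, lapply(lobe_names(), function(rg) {
          chs <- which(lob == rg)
          if (!length(chs)) return(NULL)
          rpsd <- psd
          rpsd$power <- matrix(colMeans(psd$power[chs, , drop = FALSE]), 1L)
          rpsd$channel_names <- rg
          rp <- relative_power(rpsd)
          data.frame(region = rg, band = colnames(rp), rp = as.numeric(rp),
                     stringsAsFactors = FALSE)
        }))
        df <- sub
      } else {
        rp <- relative_power(psd)
        ch_tab <- data.frame(
          channel = rep(rownames(rp), times = ncol(rp)),
          band = rep(colnames(rp), each = nrow(rp)),
          rp = as.numeric(rp), stringsAsFactors = FALSE)
        df <- aggregate_regions(ch_tab, mapping = mapping)
      }
      df$subject_id <- s$subject_id
      df$group <- s$group
      df$age <- s$age
      df$task <- task
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- do.call(rbind, rows)
  key <- if (level == "channel") "channel" else "region"
  out[, c("subject_id", "group", "age", "task", key, "band", "rp")]
}

#' Aggregate channel-level band power to scalp lobes
#'
#' Region relative power is the arithmetic mean of the member channels'
#' relative power (invariant to per-channel amplitude scaling and to
#' channel ordering). Interpolated channels are included; channels listed
#' in `exclude` are dropped before averaging.
#'
#' @param table data.frame with columns `channel`, `band`, `rp` (plus any
#'   id columns, which must be constant per channel set)
#' @param mapping optional channel-to-lobe override
#' @param exclude channel names to drop
#' @return data.frame with columns `region`, `band`, `rp`
#' @export
aggregate_regions <- function(table, mapping = NULL, exclude = character()) {
  stopifnot(all(c("channel", "band", "rp") %in% names(table)))
  tab <- table[!(table$channel %in% exclude), , drop = FALSE]
  lob <- channel_lobes(unique(tab$channel), mapping)
  tab$region <- unname(lob[tab$channel])
  out <- stats::aggregate(rp ~ region + band, data = tab, FUN = mean)
  out$region <- factor(out$region, levels = lobe_names())
  out <- out[order(out$region, out$band), ]
  out$region <- as.character(out$region)
  rownames(out) <- NULL
  out
}

#' Interpolated scalp topography grid
#'
#' Interpolates per-channel values onto a regular grid inside the unit
#' head circle using the same spherical-spline basis as channel
#' interpolation (grid points are mapped back onto the sphere through the
#' inverse azimuthal-equidistant projection). Points outside the head
#' circle are NA. The result is a numeric grid suitable for delimited
#' export, not an image.
#'
#' @param values named numeric vector (names = channels)
#' @param montage an `eeg_montage` containing those channels
#' @param n grid resolution per axis (default 32)
#' @param m,nterms,reg spherical-spline parameters
#' @return list: `x`, `y` (grid axes in [-1, 1]) and `grid` (n x n matrix,
#'   NA outside the head circle)
#' @export
topographic_grid <- function(values, montage = standard_montage_64(), n = 32,
                             m = 4, nterms = 50, reg = 1e-5) {
  if (is.null(names(values)) || length(values) < 4L)
    stop("`values` must be a named vector over at least 4 channels")
  mon <- montage_subset(montage, names(values))
  ax <- seq(-1, 1, length.out = n)
  gp <- expand.grid(x = ax, y = ax)
  r <- sqrt(gp$x^2 + gp$y^2)
  inside <- r <= 1
  chi <- r * pi / 2                       # inverse azimuthal-equidistant
  az <- atan2(gp$x, gp$y)
  P <- cbind(sin(chi) * sin(az), sin(chi) * cos(az), cos(chi))
  ng <- length(values)
  G <- .spline_g(tcrossprod(mon$pos3d), m, nterms)
  A <- rbind(cbind(G + diag(reg, ng), rep(1, ng)), c(rep(1, ng), 0))
  sol <- solve(A, c(values, 0))
  Gp <- .spline_g(P[inside, , drop = FALSE] %*% t(mon$pos3d), m, nterms)
  est <- as.numeric(Gp %*% sol[seq_len(ng)] + sol[ng + 1L])
  grid <- rep(NA_real_, n * n)
  grid[inside] <- est
  list(x = ax, y = ax, grid = matrix(grid, n, n))
}
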