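test_that("band-pass keeps in-band tones and rejects out-of-band energy", {
  fs <- 250
  keep <- sine_recording(10, fs = fs, dur = 20)
  out <- bandpass_filter(keep)
  mid <- (5 * fs):(15 * fs)   # avoid edges
  expect_equal(stats::sd(out$data[1, mid]), stats::sd(keep$data[1, mid]),
               tolerance = 0.05)
  slow <- sine_recording(0.1, fs = fs, dur = 40)
  out_slow <- bandpass_filter(slow)
  # oracle: squared (forward-backward) magnitude of the designed transfer
  # function evaluated at 0.1 Hz
  bf <- signal::butter(4, c(0.5, 45) / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * 0.1 / fs * (seq_along(bf$b) - 1))
  h <- abs(sum(bf$b * z) / sum(bf$a * z))^2
  expect_lt(h, 0.1)
  expect_lt(stats::sd(out_slow$data[1, ]), 0.1 * stats::sd(slow$data[1, ]))
  dc <- eeg_recording(matrix(3, 1, 5000), fs, "a")
  out_dc <- bandpass_filter(dc)
  expect_lt(max(abs(out_dc$data)), 0.05)
})

test_that("band-pass validates its corner frequencies", {
  rec <- sine_recording(10, dur = 4)
  expect_error(bandpass_filter(rec, 0.5, 130), "Nyquist")
  expect_error(bandpass_filter(rec, 10, 5), "low < high")
})

test_that("filtering twice barely changes in-band power (pass-band idempotence)", {
  set.seed(51)
  rec <- eeg_recording(matrix(stats::rnorm(2 * 60 * 250), 2), 250, c("a", "b"))
  f1 <- bandpass_filter(rec)
  f2 <- bandpass_filter(f1)
  bp <- function(r) {
    psd <- welch_psd(r)
    sel <- psd$frequencies >= 1 & psd$frequencies <= 40
    rowSums(psd$power[, sel])
  }
  expect_equal(bp(f2), bp(f1), tolerance = 0.1)
})

test_that("flatline bad-channel rule applies a strict 60% threshold", {
  fs <- 250; n <- 1000
  mk <- function(frac_flat) {
    x <- stats::rnorm(n) + 1   # no incidental near-zeros
    x[seq_len(round(frac_flat * n))] <- 0
    x
  }
  rec <- eeg_recording(rbind(all0 = rep(0, n), at60 = mk(0.60),
                             at61 = mk(0.61), clean = mk(0)),
                       fs, c("all0", "at60", "at61", "clean"))
  bad <- detect_bad_channels(rec)
  expect_setequal(bad, c("all0", "at61"))
  expect_error(detect_bad_channels(rec, fraction = 1.5), "fraction")
})

test_that("bad segments are maximal runs merged across channels", {
  fs <- 250
  x <- matrix(stats::rnorm(2 * 20 * fs) + 1, 2)
  rec <- eeg_recording(x, fs, c("a", "b"))
  expect_equal(nrow(detect_bad_segments(rec)), 0)
  # one 1 s window zeroed in one channel
  x1 <- x; x1[1, (5 * fs + 1):(6 * fs)] <- 0
  segs <- detect_bad_segments(eeg_recording(x1, fs, c("a", "b")))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$duration, 1, tolerance = 1.5 / fs)
  expect_equal(segs$onset, 5, tolerance = 1.5 / fs)
  # overlapping windows across channels merge to their union
  x2 <- x
  x2[1, (5 * fs + 1):(6 * fs)] <- 0
  x2[2, (5.5 * fs + 1):(6.5 * fs)] <- 0
  segs2 <- detect_bad_segments(eeg_recording(x2, fs, c("a", "b")))
  expect_equal(nrow(segs2), 1)
  expect_equal(segs2$onset, 5, tolerance = 1.5 / fs)
  expect_equal(segs2$onset + segs2$duration, 6.5, tolerance = 1.5 / fs)
  # runs below the minimum length are ignored
  x3 <- x; x3[1, 1:10] <- 0   # 40 ms < 0.2 s
  expect_equal(nrow(detect_bad_segments(eeg_recording(x3, fs, c("a", "b")))), 0)
})

test_that("spherical spline reproduces constant and first-order harmonic fields", {
  mon <- standard_montage_64()
  n_t <- 5
  # constant field
  rec <- eeg_recording(matrix(7.5, 64, n_t), 250, mon$channels)
  bad <- c("Cz", "P3")
  rec$data[match(bad, mon$channels), ] <- 99
  out <- interpolate_channels(rec, bad, mon)
  expect_equal(unname(out$data[match(bad, mon$channels), ]),
               matrix(7.5, 2, n_t), tolerance = 1e-6)
  # field = x coordinate of the electrode (first-order spherical harmonic)
  field <- mon$pos3d[, "x"]
  rec2 <- eeg_recording(matrix(field, 64, n_t), 250, mon$channels)
  bad2 <- c("C3", "CP4", "F1")
  rec2$data[match(bad2, mon$channels), ] <- 0
  out2 <- interpolate_channels(rec2, bad2, mon)
  got <- out2$data[match(bad2, mon$channels), 1]
  want <- field[match(bad2, mon$channels)]
  expect_equal(got, want, tolerance = 0.05 * max(abs(field)))
  # good channels are untouched, bit for bit
  good_idx <- !(mon$channels %in% bad2)
  expect_identical(out2$data[good_idx, ], rec2$data[good_idx, ])
})

test_that("interpolation handles the identity and degenerate cases", {
  mon <- standard_montage_64()
  rec <- eeg_recording(matrix(stats::rnorm(64 * 10), 64), 250, mon$channels)
  expect_identical(interpolate_channels(rec, character(), mon), rec)
  expect_error(interpolate_channels(rec, mon$channels[1:61], mon),
               "at least 4")
  expect_error(interpolate_channels(rec, "nope", mon), "not in recording")
})

test_that("template-correlated components are removed from frontal channels", {
  set.seed(52)
  mon <- standard_montage_64()
  cfg <- simulation_config(n_patients = 2, n_controls = 2, seed = 2,
                           task_schedule = data.frame(task = "resting",
                                                      duration = 20),
                           artifact_rates = list(flatline_channel_prob = 0,
                                                 flatline_segment_rate = 0,
                                                 blink_rate = 12))
  set.seed(53)
  rec <- generate_recording("control", "resting", 20, cfg)
  blinks <- rec$annotations[rec$annotations$label == "blink", ]
  expect_gt(nrow(blinks), 0)
  tmpl <- blink_template(rec$sampling_rate)
  ref <- numeric(ncol(rec$data))
  for (on in blinks$onset) {
    i0 <- round(on * rec$sampling_rate) + 1L
    ref[i0:(i0 + length(tmpl) - 1L)] <- ref[i0:(i0 + length(tmpl) - 1L)] + tmpl
  }
  res <- remove_artifact_components(rec, ref, threshold = 0.8)
  expect_gt(res$n_removed, 0)
  expect_true(res$removed_fraction >= 0 && res$removed_fraction <= 1)
  # blink-window variance at the frontal-most channels drops by >= 70%
  frontal <- which(mon$pos3d[, "y"] > 0.8)
  win <- unlist(lapply(blinks$onset, function(on) {
    i0 <- round(on * rec$sampling_rate) + 1L
    i0:(i0 + length(tmpl) - 1L)
  }))
  blink_var <- function(r) mean(apply(r$data[frontal, win, drop = FALSE], 1,
                                      stats::var))
  expect_lt(blink_var(res$recording), 0.3 * blink_var(rec))
})

test_that("uncorrelated references remove nothing and bounds are checked", {
  set.seed(54)
  rec <- eeg_recording(matrix(stats::rnorm(8 * 2500), 8), 250, paste0("c", 1:8))
  res <- remove_artifact_components(rec, stats::rnorm(2500), threshold = 0.8)
  expect_equal(res$n_removed, 0)
  expect_identical(res$recording$data, rec$data)
  expect_error(remove_artifact_components(rec, stats::rnorm(2500),
                                          threshold = 1.0 + 1e-9), "threshold")
  expect_error(remove_artifact_components(rec, stats::rnorm(10)), "sample")
})

test_that("QC percentages follow the stated formulas", {
  fs <- 250; dur <- 600; n_ch <- 64
  data <- matrix(stats::rnorm(n_ch * dur * fs) + 1, n_ch)
  # one 6 s flatline in one channel
  data[10, (100 * fs + 1):(106 * fs)] <- 0
  rec <- eeg_recording(data, fs, standard_montage_64()$channels)
  rep4 <- preprocess_report(rec, bad_channels = rec$channel_names[1:4])
  expect_equal(rep4$pct_bad_channels, 6.25)           # 4 / 64
  expect_equal(rep4$pct_bad_segments, 100 * 6 / (64 * 600), tolerance = 0.001)
  expect_equal(rep4$pct_artifacts_removed, 0)
  # invariant to channel ordering
  perm <- sample(n_ch)
  rec_p <- eeg_recording(data[perm, ], fs, rec$channel_names[perm])
  rep_p <- preprocess_report(rec_p, bad_channels = rec$channel_names[1:4])
  expect_equal(rep_p, rep4, tolerance = 1e-12)
})

test_that("cohort QC aggregates to mean and SD per metric", {
  reports <- rbind(
    preprocess_report(eeg_recording(matrix(1, 4, 100), 50, letters[1:4]),
                      bad_channels = "a"),
    preprocess_report(eeg_recording(matrix(1, 4, 100), 50, letters[1:4])))
  qc <- qc_summary(reports)
  expect_equal(qc$summary$mean[qc$summary$metric == "pct_bad_channels"], 12.5)
  expect_equal(qc$summary$sd[qc$summary$metric == "pct_bad_channels"],
               stats::sd(c(25, 0)))
})

test_that("resting recordings are cropped to the first two minutes", {
  fs <- 250
  long <- eeg_recording(matrix(stats::rnorm(420 * fs), 1), fs, "a")
  out <- crop_resting(long)
  expect_equal(ncol(out$data), 120 * fs)
  expect_identical(out$data[1, ], long$data[1, seq_len(120 * fs)])
  exact <- eeg_recording(matrix(stats::rnorm(120 * fs), 1), fs, "a")
  expect_equal(ncol(crop_resting(exact)$data), 120 * fs)
  short <- eeg_recording(matrix(stats::rnorm(90 * fs), 1), fs, "a")
  expect_warning(out_s <- crop_resting(short), "full length")
  expect_equal(ncol(out_s$data), 90 * fs)
})

test_that("the preprocessing chain flags, repairs and reports", {
  set.seed(55)
  mon <- standard_montage_64()
  cfg <- simulation_config(n_patients = 2, n_controls = 2, seed = 3,
                           task_schedule = data.frame(task = "resting",
                                                      duration = 12))
  set.seed(56)
  rec <- generate_recording("control", "resting", 12, cfg)
  rec$data[5, ] <- 0                                   # dead channel
  rec$data[20, (4 * 250):(6 * 250)] <- 0               # transient flatline
  res <- preprocess_recording(rec, mon)
  expect_equal(res$recording$bad_channels, mon$channels[5])
  expect_gte(nrow(res$recording$bad_segments), 1)
  # the dead channel was reconstructed, not left flat
  expect_gt(stats::sd(res$recording$data[5, ]), 0.1)
  expect_equal(res$report$pct_bad_channels, 100 / 64)
  expect_gt(res$report$pct_bad_segments, 0)
})
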