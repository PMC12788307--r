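test_that("cohort generation honours sizes, metadata and determinism", {
  cfg <- simulation_config(n_patients = 21, n_controls = 37, seed = 7,
                           task_schedule = data.frame(task = "resting",
                                                      duration = 2))
  coh <- generate_cohort(cfg)
  expect_length(coh$subjects, 58)
  expect_equal(nrow(coh$metadata), 58)
  expect_equal(sum(coh$metadata$group == "patient"), 21)
  expect_equal(sum(coh$metadata$group == "control"), 37)
  expect_true(all(coh$metadata$age >= 23 & coh$metadata$age <= 80))
  expect_true(all(coh$metadata$sex %in% c("M", "F")))
  # byte-identical reproduction under the same config
  cfg2 <- simulation_config(n_patients = 2, n_controls = 2, seed = 1,
                            task_schedule = data.frame(task = "resting",
                                                       duration = 3))
  expect_identical(serialize(generate_cohort(cfg2), NULL),
                   serialize(generate_cohort(cfg2), NULL))
})

test_that("configuration errors name the offending field", {
  expect_error(simulation_config(n_patients = 1), "n_patients",
               class = "eegfc_config_error")
  expect_error(simulation_config(sampling_rate = 80), "sampling_rate")
  expect_error(simulation_config(
    task_schedule = data.frame(task = "resting", duration = -1)),
    "task_schedule")
  g <- default_band_gains()
  g[1] <- -1
  expect_error(simulation_config(band_gains = g), "band_gains")
  expect_error(
    generate_cohort(simulation_config(), tasks = "no_such_task"),
    "unknown task")
})

test_that("zero gains and zero exponent give a flat white spectrum", {
  cfg <- simulation_config(n_patients = 2, n_controls = 2, seed = 4,
                           background_exponent = 0,
                           task_schedule = data.frame(task = "resting",
                                                      duration = 60))
  cfg$band_gains[] <- 0
  set.seed(57)
  rec <- generate_recording("control", "resting", 60, cfg)
  psd <- welch_psd(rec)
  sel <- psd$frequencies >= 1 & psd$frequencies <= 40
  cv <- apply(psd$power[1:8, sel], 1, function(p) stats::sd(p) / mean(p))
  expect_true(all(cv < 0.35))
  # fitted log-log slope ~ 0
  lp <- log(colMeans(psd$power[, sel]))
  slope <- stats::coef(stats::lm(lp ~ log(psd$frequencies[sel])))[2]
  expect_lt(abs(slope), 0.2)
})

test_that("the 1/f background slope is recovered from the average spectrum", {
  cfg <- simulation_config(n_patients = 5, n_controls = 5, seed = 8,
                           background_exponent = 1.2,
                           task_schedule = data.frame(task = "resting",
                                                      duration = 30))
  cfg$band_gains[] <- 0
  coh <- generate_cohort(cfg)
  acc <- NULL
  for (s in coh$subjects) {
    psd <- welch_psd(s$recordings$resting)
    acc <- if (is.null(acc)) psd$power else acc + psd$power
  }
  psd$power <- acc / length(coh$subjects)
  sel <- psd$frequencies >= 1 & psd$frequencies <= 40
  slope <- stats::coef(stats::lm(log(colMeans(psd$power[, sel])) ~
                                   log(psd$frequencies[sel])))[2]
  expect_equal(unname(slope), -1.2, tolerance = 0.2)
})

test_that("doubling one region's alpha gain quadruples its alpha band power", {
  cfg <- simulation_config(n_patients = 2, n_controls = 2, seed = 9,
                           background_rms = 0.5, subject_sd = 0,
                           task_schedule = data.frame(task = "resting",
                                                      duration = 60))
  cfg$band_gains <- set_band_gain(cfg$band_gains, "patient", "parietal",
                                  "resting", "alpha", multiply = 2)
  set.seed(58)
  rec <- generate_recording("patient", "resting", 60, cfg)
  # oracle: direct periodogram of the generated signal
  mon <- cfg$montage
  band_power <- function(ch) {
    x <- rec$data[ch, ]
    n <- length(x)
    p <- abs(stats::fft(x))^2 / n
    f <- (seq_len(n) - 1) * rec$sampling_rate / n
    sum(p[f >= 8 & f < 13])
  }
  par_ch <- which(mon$lobe == "parietal")
  cen_ch <- which(mon$lobe == "central")
  # same baseline alpha gain in central; parietal baseline is 6 vs 4,
  # so compare against the expected (2 * 6 / 4)^2 ratio
  ratio <- mean(vapply(par_ch, band_power, 0)) /
    mean(vapply(cen_ch, band_power, 0))
  expect_equal(ratio, (2 * 6 / 4)^2, tolerance = 0.2 * (2 * 6 / 4)^2)
})

test_that("flatline and blink artifacts are injected on demand", {
  cfg <- simulation_config(n_patients = 2, n_controls = 2, seed = 10,
                           task_schedule = data.frame(task = "resting",
                                                      duration = 30),
                           artifact_rates = list(flatline_channel_prob = 0.05,
                                                 flatline_segment_rate = 6,
                                                 blink_rate = 6))
  set.seed(59)
  rec <- generate_recording("control", "resting", 30, cfg)
  segs <- detect_bad_segments(rec)
  expect_gte(nrow(segs), 1)
  expect_gte(sum(rec$annotations$label == "blink"), 1)
})

test_that("a patient alpha elevation shows up as a mean power difference", {
  cfg <- simulation_config(n_patients = 25, n_controls = 25, seed = 11,
                           task_schedule = data.frame(task = "resting",
                                                      duration = 15))
  cfg$band_gains <- set_band_gain(cfg$band_gains, "patient", "parietal",
                                  "resting", "alpha", multiply = 1.6)
  coh <- generate_cohort(cfg)
  tab <- cohort_band_power(coh)
  cell <- tab[tab$region == "parietal" & tab$band == "alpha", ]
  expect_gt(mean(cell$rp[cell$group == "patient"]),
            mean(cell$rp[cell$group == "control"]))
})

test_that("effect calibration brackets the target and respects its sign", {
  cfg <- simulation_config(n_patients = 12, n_controls = 12, seed = 12,
                           task_schedule = data.frame(task = "resting",
                                                      duration = 20))
  expect_equal(calibrate_effect("alpha", "parietal", "resting", 0, cfg)$ratio, 1)
  cal_up <- calibrate_effect("alpha", "parietal", "resting", 0.6, cfg,
                             pilot_n = 30, pilot_duration = 15)
  expect_gt(cal_up$ratio, 1)
  expect_lt(abs(cal_up$d - 0.6), 0.15)
  cal_dn <- calibrate_effect("gamma", "temporal", "resting", -0.6, cfg,
                             pilot_n = 30, pilot_duration = 15)
  expect_lt(cal_dn$ratio, 1)
  expect_error(calibrate_effect("alpha", "parietal", "resting", 0.6, cfg,
                                pilot_n = 5), "pilot_n")
  # unreachable target reports the best ratio found
  expect_error(calibrate_effect("alpha", "parietal", "resting", 50, cfg,
                                pilot_n = 10, pilot_duration = 10),
               "best ratio", class = "eegfc_calibration_error")
})

test_that("a calibrated ratio reproduces its effect size out of sample", {
  cfg <- simulation_config(n_patients = 12, n_controls = 12, seed = 13,
                           task_schedule = data.frame(task = "resting",
                                                      duration = 15))
  cal <- calibrate_effect("alpha", "parietal", "resting", 0.6, cfg,
                          pilot_n = 80, pilot_duration = 15,
                          tol = 0.05, max_iter = 20)
  big <- cfg
  big$n_patients <- 200; big$n_controls <- 200; big$seed <- 14
  big$band_gains <- set_band_gain(big$band_gains, "patient", "parietal",
                                  "resting", "alpha", multiply = cal$ratio)
  coh <- generate_cohort(big)
  tab <- cohort_band_power(coh)
  cell <- tab[tab$region == "parietal" & tab$band == "alpha", ]
  d <- cohens_d(cell$rp[cell$group == "patient"],
                cell$rp[cell$group == "control"])
  expect_gt(d, 0.45)
  expect_lt(d, 0.75)
})
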