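#' Default task schedule
#'
#' The experimental paradigm modelled by the simulator: an eyes-open
#' resting baseline, a cognitive block, and defecation-related imagery /
#' strain tasks. Durations are in seconds and configurable; the simulated
#' strain blocks consist of cycles of holding and relaxing whose timing is
#' exposed via `cycle_timing` in [simulation_config()].
#'
#' @return data.frame with columns `task` and `duration` (s)
#' @export
default_task_schedule <- function() {
  data.frame(
    task = c("resting", "cognitive", "imaginary_defecation", "simulated_defecation",
             "imaginary_anal_contraction", "anal_contraction"),
    duration = c(420, 160, 30, 250, 30, 250),
    stringsAsFactors = FALSE
  )
}

#' Canonical EEG frequency bands
#'
#' Delta through gamma, tiling 0.5-45 Hz without overlap.
#'
#' @return data.frame with columns `band`, `f_low`, `f_high`
#' @export
band_definitions <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    f_low = c(0.5, 4, 8, 13, 30),
    f_high = c(4, 8, 13, 30, 45),
    stringsAsFactors = FALSE
  )
}

#' Default oscillator amplitude table
#'
#' A 4-dimensional array of band-limited oscillator amplitudes (microvolt
#' RMS) indexed by group x region x task x band. The baseline emulates the
#' canonical resting spectrum: posterior-dominant alpha, appreciable
#' delta/theta, weaker beta and gamma; both groups start identical so that
#' group effects are injected explicitly (see [set_band_gain()] and
#' [calibrate_effect()]).
#'
#' @param tasks character vector of task names
#' @return numeric array with dimnames (group, region, task, band)
#' @export
default_band_gains <- function(tasks = default_task_schedule()$task) {
  bands <- band_definitions()$band
  regions <- lobe_names()
  base <- c(delta = 4, theta = 3, alpha = 4, beta = 2, gamma = 1)
  g <- array(0, dim = c(2, length(regions), length(tasks), length(bands)),
             dimnames = list(group = c("patient", "control"), region = regions,
                             task = tasks, band = bands))
  for (b in bands) g[, , , b] <- base[[b]]
  # posterior alpha dominance
  g[, c("parietal", "occipital"), , "alpha"] <- 6
  g
}

#' Set (scale) one oscillator amplitude cell
#'
#' @param gains array from [default_band_gains()]
#' @param group,region,task,band index labels; any may be a vector
#' @param value absolute amplitude, or NULL to use `multiply`
#' @param multiply multiplicative factor applied instead of `value`
#' @export
set_band_gain <- function(gains, group, region, task, band,
                          value = NULL, multiply = NULL) {
  if (is.null(value) == is.null(multiply))
    stop("give exactly one of `value` or `multiply`")
  if (is.null(value)) {
    gains[group, region, task, band] <- gains[group, region, task, band] * multiply
  } else {
    gains[group, region, task, band] <- value
  }
  gains
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults model
#' the study conditions: 64-channel 10-10 montage at 250 Hz, the task
#' schedule of [default_task_schedule()], a 1/f background with exponent
#' 1, region-shared lagged oscillator sources (so imaginary coherence is
#' non-zero), log-normal between-subject amplitude variability, and no
#' artifacts unless rates are raised.
#'
#' @param n_patients,n_controls group sizes (each >= 2)
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the configuration including this seed
#' @param sampling_rate Hz (must exceed 90 Hz = twice the top band edge)
#' @param montage an `eeg_montage`
#' @param task_schedule data.frame (task, duration s)
#' @param background_exponent 1/f slope of the background (power ~ f^-e)
#' @param background_rms background amplitude, microvolt RMS
#' @param band_gains array from [default_band_gains()]
#' @param shared_fraction fraction of each oscillator's variance drawn
#'   from the region-shared lagged source (controls imaginary coherence)
#' @param subject_sd sd of the per-subject log-normal band amplitude
#'   multiplier (between-subject variability)
#' @param artifact_rates list: `flatline_channel_prob` (per channel),
#'   `flatline_segment_rate` and `blink_rate` (events per minute)
#' @param age_ranges list of c(min, max) years per group
#' @param age_confound if TRUE, patient ages are drawn from the upper half
#'   of their range (for exercising the ANCOVA adjustment)
#' @param prob_female probability a simulated subject is female
#' @param cycle_timing c(hold, relax) seconds for strain-task cycles;
#'   annotated on the simulated strain blocks
#' @return object of class `sim_config`
#' @export
simulation_config <- function(n_patients = 21, n_controls = 37, seed = 1,
                              sampling_rate = 250,
                              montage = standard_montage_64(),
                              task_schedule = default_task_schedule(),
                              background_exponent = 1,
                              background_rms = 10,
                              band_gains = default_band_gains(task_schedule$task),
                              shared_fraction = 0.6,
                              subject_sd = 0.25,
                              artifact_rates = list(flatline_channel_prob = 0,
                                                    flatline_segment_rate = 0,
                                                    blink_rate = 0),
                              age_ranges = list(patient = c(23, 80),
                                                control = c(23, 80)),
                              age_confound = FALSE,
                              prob_female = 0.7,
                              cycle_timing = c(hold = 5, relax = 10)) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  .validate_sim_config(cfg)
  cfg
}

.sim_config_error <- function(field, msg) {
  stop(structure(class = c("eegfc_config_error", "error", "condition"),
                 list(message = sprintf("invalid `%s`: %s", field, msg),
                      call = NULL, field = field)))
}

.validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 2)
    .sim_config_error("n_patients", "need at least 2 per group")
  if (!is.numeric(cfg$n_controls) || cfg$n_controls < 2)
    .sim_config_error("n_controls", "need at least 2 per group")
  if (cfg$sampling_rate <= 2 * 45)
    .sim_config_error("sampling_rate", "must exceed twice the 45 Hz top band edge")
  if (!all(cfg$task_schedule$duration > 0))
    .sim_config_error("task_schedule", "all task durations must be > 0")
  if (any(cfg$band_gains < 0))
    .sim_config_error("band_gains", "amplitudes must be >= 0")
  if (cfg$shared_fraction < 0 || cfg$shared_fraction > 1)
    .sim_config_error("shared_fraction", "must be in [0, 1]")
  rates <- cfg$artifact_rates
  need <- c("flatline_channel_prob", "flatline_segment_rate", "blink_rate")
  if (!all(need %in% names(rates)) || any(unlist(rates[need]) < 0))
    .sim_config_error("artifact_rates", paste("must contain non-negative",
                                              paste(need, collapse = ", ")))
  for (g in c("patient", "control")) {
    r <- cfg$age_ranges[[g]]
    if (is.null(r) || length(r) != 2L || r[1] > r[2])
      .sim_config_error("age_ranges", paste("need c(min, max) for", g))
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d patients + %d controls, %d ch @ %g Hz, seed %d\n",
              x$n_patients, x$n_controls, length(x$montage$channels),
              x$sampling_rate, x$seed))
  invisible(x)
}

# Hermitian-symmetric inverse FFT of half-spectra (bins 2..nh+1), one
# column per channel; returns an n x ncol matrix of real zero-mean signals.
.half_spectra_to_signals <- function(H, n) {
  nh <- nrow(H)
  spec <- matrix(complex(real = 0), n, ncol(H))
  spec[2:(nh + 1L), ] <- H
  spec[n:(n - nh + 1L), ] <- Conj(H)
  Re(stats::mvfft(spec, inverse = TRUE)) / n
}

.crnorm <- function(n) complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))

#' Stereotyped blink transient
#'
#' Biphasic eye-blink waveform (positive lobe followed by a smaller
#' negative rebound) used both to inject ocular artifacts and as the
#' reference template for the artifact-removal stand-in.
#'
#' @param sampling_rate Hz
#' @param duration seconds (default 0.4)
#' @param amplitude peak amplitude in microvolts
#' @return numeric vector of length `duration * sampling_rate`
#' @export
blink_template <- function(sampling_rate, duration = 0.4, amplitude = 120) {
  t <- seq(0, duration, length.out = round(duration * sampling_rate))
  env <- sin(pi * t / duration)^2
  amplitude * env * (1.2 * exp(-((t - 0.35 * duration) / (0.18 * duration))^2) -
                     0.5 * exp(-((t - 0.7 * duration) / (0.25 * duration))^2))
}

#' Generate one synthetic task-block recording
#'
#' Signal model: each channel is an independent 1/f background plus, for
#' every band x region, a band-limited oscillator built in the frequency
#' domain as a mixture of a region-shared source (per-channel uniform
#' phase lag, so coupling survives the imaginary part of coherency) and
#' channel-private noise. Oscillator RMS amplitudes come from the
#' `band_gains` table scaled by the subject's per-band multiplier.
#' Optional flatline and blink artifacts are injected last and annotated.
#'
#' @param group "patient" or "control"
#' @param task task name (must index `band_gains`)
#' @param duration seconds
#' @param config a `sim_config`
#' @param subject_multiplier named per-band amplitude multipliers
#'   (default all 1)
#' @return an `eeg_recording` (blink annotations carry label "blink")
#' @details Uses the current RNG state; callers seed it. Determinism of a
#'   cohort therefore reduces to seeding once per subject.
#' @export
generate_recording <- function(group, task, duration, config,
                               subject_multiplier = NULL) {
  mon <- config$montage
  n_ch <- length(mon$channels)
  fs <- config$sampling_rate
  n <- round(duration * fs)
  if (n < 2) .sim_config_error("task_schedule", "task duration too short")
  bands <- band_definitions()
  if (is.null(subject_multiplier))
    subject_multiplier <- stats::setNames(rep(1, nrow(bands)), bands$band)
  lobes <- as.character(mon$lobe)
  if (anyNA(lobes)) stop("montage channel without region mapping")

  nh <- floor((n - 1) / 2)           # usable half-spectrum bins
  freq <- (1:nh) * fs / n
  x <- matrix(0, n_ch, n)

  # One half-spectrum per channel accumulates background and all
  # oscillators; a single inverse FFT then realizes the recording.
  # Components are normalized to their expected RMS: a half-spectrum with
  # E|H_k|^2 = 2 yields a signal of expected variance 4 * nbins / n^2.
  H <- matrix(complex(real = 0), nh, n_ch)

  # 1/f background, independent per channel
  if (config$background_rms > 0) {
    shape <- pmax(freq, 0.5)^(-config$background_exponent / 2)
    scale_bg <- config$background_rms * n / (2 * sqrt(sum(shape^2)))
    H <- H + matrix(.crnorm(nh * n_ch), nh, n_ch) * (shape * scale_bg)
  }

  # band-limited oscillators, region-shared lagged source + private noise
  sf <- config$shared_fraction
  for (b in seq_len(nrow(bands))) {
    sel <- which(freq >= bands$f_low[b] & freq < bands$f_high[b])
    if (!length(sel)) next
    gains <- config$band_gains[group, lobes, task, bands$band[b]] *
      subject_multiplier[[bands$band[b]]]
    scale_b <- gains * n / (2 * sqrt(length(sel)))   # per channel
    for (rg in lobe_names()) {
      chs <- which(lobes == rg)
      if (!length(chs)) next
      shared <- .crnorm(length(sel))
      phase <- stats::runif(length(chs), 0, 2 * pi)
      priv <- matrix(.crnorm(length(sel) * length(chs)), length(sel))
      osc <- sqrt(sf) * outer(shared, exp(1i * phase)) + sqrt(1 - sf) * priv
      H[sel, chs] <- H[sel, chs] + osc * rep(scale_b[chs], each = length(sel))
    }
  }
  x <- t(.half_spectra_to_signals(H, n))

  ann <- NULL
  rates <- config$artifact_rates
  minutes <- duration / 60
  # whole-channel flatline (bad-channel material)
  flat_ch <- which(stats::runif(n_ch) < rates$flatline_channel_prob)
  x[flat_ch, ] <- 0
  # transient flatline segments in single channels
  n_seg <- stats::rpois(1, rates$flatline_segment_rate * minutes)
  seg_rows <- NULL
  if (n_seg > 0) {
    for (i in seq_len(n_seg)) {
      d <- stats::runif(1, 0.3, 1)
      on <- stats::runif(1, 0, max(duration - d, 0))
      ch <- sample(setdiff(seq_len(n_ch), flat_ch), 1)
      i0 <- max(1L, round(on * fs)); i1 <- min(n, round((on + d) * fs))
      x[ch, i0:i1] <- 0
      seg_rows <- rbind(seg_rows, data.frame(onset = on, duration = d,
                                             label = "flatline"))
    }
  }
  # blinks: biphasic transient weighted by a frontal spatial profile
  n_blink <- stats::rpois(1, rates$blink_rate * minutes)
  if (n_blink > 0) {
    tmpl <- blink_template(fs)
    w <- pmax(mon$pos3d[, "y"], 0)^3
    onsets <- sort(stats::runif(n_blink, 0, duration - length(tmpl) / fs))
    for (on in onsets) {
      i0 <- round(on * fs) + 1L
      idx <- i0:(i0 + length(tmpl) - 1L)
      x[, idx] <- x[, idx] + outer(w, tmpl)
    }
    ann <- data.frame(onset = onsets, duration = length(tmpl) / fs,
                      label = "blink")
  }
  ann <- rbind(ann, seg_rows)
  eeg_recording(x, fs, mon$channels, annotations = ann)
}

#' Generate a synthetic two-group cohort
#'
#' Draws `n_patients + n_controls` subjects with ages, sexes, per-subject
#' band-amplitude multipliers and one recording per scheduled task block.
#' Deterministic: the same configuration (including `seed`) reproduces the
#' cohort exactly.
#'
#' @param config a `sim_config`
#' @param tasks optional subset of schedule task names to generate
#' @return object of class `eeg_cohort`: list with `subjects` (each a list
#'   subject_id/group/age/sex/multipliers/recordings) and `metadata`
#'   (one data.frame row per subject)
#' @examples
#' cfg <- simulation_config(n_patients = 2, n_controls = 2, seed = 1,
#'   task_schedule = data.frame(task = "resting", duration = 4))
#' coh <- generate_cohort(cfg)
#' coh$metadata
#' @export
generate_cohort <- function(config, tasks = NULL) {
  .validate_sim_config(config)
  sched <- config$task_schedule
  if (!is.null(tasks)) {
    missing <- setdiff(tasks, sched$task)
    if (length(missing)) .sim_config_error("task_schedule",
                                           paste("unknown task:", missing[1]))
    sched <- sched[sched$task %in% tasks, , drop = FALSE]
  }
  groups <- c(rep("patient", config$n_patients), rep("control", config$n_controls))
  ids <- c(sprintf("P%02d", seq_len(config$n_patients)),
           sprintf("C%02d", seq_len(config$n_controls)))
  set.seed(config$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, length(ids))
  bands <- band_definitions()$band

  subjects <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    set.seed(subject_seeds[i])
    rng_age <- config$age_ranges[[groups[i]]]
    if (config$age_confound && groups[i] == "patient")
      rng_age <- c(mean(rng_age), rng_age[2])
    age <- round(stats::runif(1, rng_age[1], rng_age[2]), 1)
    sex <- if (stats::runif(1) < config$prob_female) "F" else "M"
    mult <- stats::setNames(exp(stats::rnorm(length(bands), 0, config$subject_sd)),
                            bands)
    recs <- list()
    for (j in seq_len(nrow(sched))) {
      recs[[sched$task[j]]] <- generate_recording(
        groups[i], sched$task[j], sched$duration[j], config,
        subject_multiplier = mult)
    }
    subjects[[i]] <- list(subject_id = ids[i], group = groups[i], age = age,
                          sex = sex, multipliers = mult, recordings = recs)
  }
  metadata <- data.frame(
    subject_id = ids, group = groups,
    age = vapply(subjects, `[[`, 0, "age"),
    sex = vapply(subjects, `[[`, "", "sex"),
    seed = subject_seeds, stringsAsFactors = FALSE
  )
  structure(list(subjects = subjects, metadata = metadata, config = config),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> %d subjects (%d patients, %d controls), %d task(s)\n",
              nrow(x$metadata), sum(x$metadata$group == "patient"),
              sum(x$metadata$group == "control"),
              length(x$subjects[[1]]$recordings)))
  invisible(x)
}

#' Write a cohort to disk as EDF plus metadata table
#'
#' One EDF per subject per task (`<subject>_<task>.edf`) and a
#' `metadata.csv` with subject_id, group, age, sex and the per-subject
#' seed.
#'
#' @param cohort an `eeg_cohort`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    for (task in names(s$recordings)) {
      write_edf(s$recordings[[task]],
                file.path(dir, sprintf("%s_%s.edf", s$subject_id, task)),
                patient_id = s$subject_id, recording_id = task)
    }
  }
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Calibrate a group amplitude ratio to a target effect size
#'
#' Finds the patient/control oscillator-amplitude ratio for one
#' (band, region, task) cell such that the Cohen's d of the cell's
#' relative power in a pilot simulation matches `target_d`. Searches by
#' bisection on log-ratio. Pilot subjects are simulated pairwise with
#' common random numbers (each virtual patient shares its control twin's
#' amplitude multipliers and noise realization, differing only in the
#' candidate gain ratio) and only the target region's channels are
#' generated; both choices cut pilot variance and cost by an order of
#' magnitude without changing what is being measured.
#'
#' @param band,region,task the cell to calibrate
#' @param target_d target Cohen's d (patient minus control convention)
#' @param config a `sim_config` used for the pilot cohorts
#' @param pilot_n pilot subjects per group (>= 10)
#' @param pilot_duration pilot task-block length in seconds
#' @param tol acceptable |d - target_d| (default 0.15)
#' @param max_iter bisection iterations before giving up
#' @param ratio_bounds search interval for the ratio
#' @return list with `ratio`, achieved `d`, and `iterations`
#' @export
calibrate_effect <- function(band, region, task, target_d, config,
                             pilot_n = 60, pilot_duration = 20,
                             tol = 0.15, max_iter = 12,
                             ratio_bounds = c(1 / 8, 8)) {
  if (!is.finite(target_d)) stop("`target_d` must be finite")
  if (pilot_n < 10) stop("`pilot_n` must be >= 10 per group")
  if (target_d == 0) return(list(ratio = 1, d = 0, iterations = 0L))
  if (!task %in% config$task_schedule$task) stop("unknown task: ", task)

  mon <- config$montage
  cfg <- config
  cfg$montage <- montage_subset(mon, mon$channels[mon$lobe == region])
  bands <- band_definitions()$band
  base_seed <- config$seed

  pilot_rp <- function(group, ratio, i) {
    set.seed(base_seed + i)
    mult <- stats::setNames(exp(stats::rnorm(length(bands), 0,
                                             config$subject_sd)), bands)
    cfg_i <- cfg
    if (ratio != 1)
      cfg_i$band_gains <- set_band_gain(cfg_i$band_gains, "patient", region,
                                        task, band, multiply = ratio)
    rec <- generate_recording(group, task, pilot_duration, cfg_i,
                              subject_multiplier = mult)
    mean(relative_power(welch_psd(rec))[, band])
  }
  ctl <- vapply(seq_len(pilot_n), function(i) pilot_rp("control", 1, i), 0)
  d_of <- function(r) {
    pat <- vapply(seq_len(pilot_n), function(i) pilot_rp("patient", r, i), 0)
    cohens_d(pat, ctl)
  }

  lo <- ratio_bounds[1]; hi <- ratio_bounds[2]
  d_lo <- d_of(lo); d_hi <- d_of(hi)
  if (!(d_lo < target_d && target_d < d_hi)) {
    best <- if (abs(d_lo - target_d) < abs(d_hi - target_d)) lo else hi
    .calibration_error(best, if (best == lo) d_lo else d_hi, target_d)
  }
  r <- NA_real_; d <- NA_real_
  for (it in seq_len(max_iter)) {
    r <- exp((log(lo) + log(hi)) / 2)
    d <- d_of(r)
    if (abs(d - target_d) <= tol)
      return(list(ratio = r, d = d, iterations = it))
    if (d < target_d) lo <- r else hi <- r
  }
  .calibration_error(r, d, target_d)
}

.calibration_error <- function(ratio, d, target) {
  stop(structure(class = c("eegfc_calibration_error", "error", "condition"),
                 list(message = sprintf(
                   "calibration did not converge: best ratio %.4g gives d = %.3f (target %.3f)",
                   ratio, d, target), call = NULL, ratio = ratio, d = d)))
}
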