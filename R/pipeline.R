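#' Assemble a full pipeline configuration
#'
#' One configuration object drives simulate -> preprocess -> features ->
#' stats. Every default reproduces the packaged end-to-end demo; all
#' values can be overridden here or via a YAML file
#' (see [read_pipeline_config()]).
#'
#' @param out_dir run directory for all outputs
#' @param simulation a `sim_config` (see [simulation_config()])
#' @param preprocessing list: `low`, `high` (filter band, Hz),
#'   `flat_fraction`, `flat_amp`, `min_run` (flatline rules),
#'   `crop_resting_s` (resting analysis window), `artifact_removal`
#'   (logical), `artifact_threshold`
#' @param spectral list: `window` (s), `overlap`, `average_spectra`
#' @param bands band table (default [band_definitions()])
#' @param sparsity ascending sparsity grid
#' @param stats list: `alpha`, `fdr_network`
#' @param seed integer; overrides `simulation$seed` so one flag controls
#'   all randomness
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir = tempfile("eegfc_run_"),
                            simulation = simulation_config(),
                            preprocessing = list(),
                            spectral = list(),
                            bands = band_definitions(),
                            sparsity = sparsity_grid(),
                            stats = list(),
                            seed = NULL) {
  pre_def <- list(low = 0.5, high = 45, flat_fraction = 0.60,
                  flat_amp = 1e-10, min_run = 0.2, crop_resting_s = 120,
                  artifact_removal = FALSE, artifact_threshold = 0.8)
  spec_def <- list(window = 2, overlap = 0.5, average_spectra = FALSE)
  stat_def <- list(alpha = 0.05, fdr_network = FALSE)
  preprocessing <- utils::modifyList(pre_def, preprocessing)
  spectral <- utils::modifyList(spec_def, spectral)
  stats <- utils::modifyList(stat_def, stats)
  if (!is.null(seed)) simulation$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, simulation = simulation,
                 preprocessing = preprocessing, spectral = spectral,
                 bands = bands, sparsity = sparsity, stats = stats),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks every section invariant and returns the problems found (empty
#' character vector when the configuration is valid). Never raises and
#' never mutates.
#'
#' @param config a `pipeline_config`
#' @return character vector of problem descriptions
#' @export
validate_config <- function(config) {
  probs <- character()
  add <- function(msg) probs <<- c(probs, msg)
  sim_ok <- tryCatch({ .validate_sim_config(config$simulation); TRUE },
                     error = function(e) { add(conditionMessage(e)); FALSE })
  p <- config$preprocessing
  if (!(p$low > 0 && p$low < p$high))
    add("preprocessing: need 0 < low < high")
  if (sim_ok && p$high >= config$simulation$sampling_rate / 2)
    add("preprocessing: `high` must be below the Nyquist frequency")
  if (!(p$flat_fraction > 0 && p$flat_fraction < 1))
    add("preprocessing: `flat_fraction` must be in (0, 1)")
  if (p$min_run <= 0) add("preprocessing: `min_run` must be > 0")
  s <- config$spectral
  if (s$window <= 0) add("spectral: `window` must be > 0")
  if (!(s$overlap >= 0 && s$overlap < 1))
    add("spectral: `overlap` must be in [0, 1)")
  b <- config$bands
  if (is.unsorted(b$f_low) || any(b$f_high[-nrow(b)] != b$f_low[-1])) {
    ov <- which(b$f_high[-nrow(b)] != b$f_low[-1])
    add(sprintf("bands: `%s` and `%s` do not tile contiguously",
                b$band[ov[1]], b$band[ov[1] + 1]))
  }
  if (any(b$f_low >= b$f_high)) add("bands: f_low must be < f_high")
  sp <- config$sparsity
  if (length(sp) < 2 || is.unsorted(sp, strictly = TRUE))
    add("sparsity: grid must be >= 2 strictly ascending values")
  if (any(sp <= 0 | sp > 1)) add("sparsity: values must be in (0, 1]")
  st <- config$stats
  if (!(st$alpha > 0 && st$alpha < 1)) add("stats: `alpha` must be in (0, 1)")
  probs
}

#' Read / write pipeline configurations as YAML
#'
#' A flat, human-editable file with sections mirroring
#' [pipeline_config()]. Group-effect injections are expressed as an
#' `effects` list of (group, region, task, band, multiply) entries
#' applied on top of [default_band_gains()].
#'
#' @param path YAML file path
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation %||% list()
  keep <- intersect(names(sim_args),
                    c("n_patients", "n_controls", "seed", "sampling_rate",
                      "background_exponent", "background_rms",
                      "shared_fraction", "subject_sd", "prob_female",
                      "age_confound"))
  sim_args <- sim_args[keep]
  if (!is.null(y$task_schedule))
    sim_args$task_schedule <- do.call(rbind, lapply(y$task_schedule, function(t)
      data.frame(task = t$task, duration = t$duration)))
  sim <- do.call(simulation_config, sim_args)
  if (!is.null(y$artifact_rates))
    sim$artifact_rates <- utils::modifyList(sim$artifact_rates, y$artifact_rates)
  for (e in y$effects %||% list())
    sim$band_gains <- set_band_gain(sim$band_gains, e$group, e$region, e$task,
                                    e$band, multiply = e$multiply)
  pipeline_config(out_dir = y$out_dir %||% tempfile("eegfc_run_"),
                  simulation = sim,
                  preprocessing = y$preprocessing %||% list(),
                  spectral = y$spectral %||% list(),
                  sparsity = unlist(y$sparsity %||% sparsity_grid()),
                  stats = y$stats %||% list(),
                  seed = y$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preprocess every recording of a cohort
#'
#' Applies [preprocess_recording()] (with resting-block cropping) to each
#' subject and task, replacing the recordings in place and collecting the
#' per-subject QC reports.
#'
#' @param cohort an `eeg_cohort`
#' @param config a `pipeline_config`
#' @return list: `cohort` (recordings cleaned), `qc` (from
#'   [qc_summary()])
#' @export
preprocess_cohort <- function(cohort, config = pipeline_config()) {
  p <- config$preprocessing
  mon <- cohort$config$montage
  reports <- list()
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    per_rec <- list()
    for (task in names(s$recordings)) {
      rec <- s$recordings[[task]]
      if (task == "resting" &&
          recording_duration(rec) >= p$crop_resting_s)
        rec <- crop_resting(rec, p$crop_resting_s)
      ref <- NULL
      if (isTRUE(p$artifact_removal))
        ref <- .blink_reference(rec)
      res <- preprocess_recording(rec, mon, p$low, p$high, p$flat_fraction,
                                  p$flat_amp, p$min_run,
                                  artifact_reference = ref,
                                  artifact_threshold = p$artifact_threshold)
      cohort$subjects[[i]]$recordings[[task]] <- res$recording
      per_rec[[task]] <- res$report
    }
    rep_i <- do.call(rbind, per_rec)
    reports[[s$subject_id]] <- data.frame(subject_id = s$subject_id,
                                          t(colMeans(rep_i)))
  }
  list(cohort = cohort, qc = qc_summary(do.call(rbind, reports)))
}

# blink reference train built from the recording's own annotations
.blink_reference <- function(rec) {
  ann <- rec$annotations
  ann <- ann[ann$label == "blink", , drop = FALSE]
  if (!nrow(ann)) return(NULL)
  tmpl <- blink_template(rec$sampling_rate)
  ref <- numeric(ncol(rec$data))
  for (on in ann$onset) {
    i0 <- round(on * rec$sampling_rate) + 1L
    idx <- i0:min(i0 + length(tmpl) - 1L, length(ref))
    ref[idx] <- ref[idx] + tmpl[seq_along(idx)]
  }
  ref
}

#' Run the full pipeline
#'
#' simulate -> preprocess -> features (band power, connectivity, network
#' topology) -> group statistics, writing every intermediate table to the
#' run directory together with a manifest (configuration fingerprint,
#' seed, per-stage wall time). Deterministic: rerunning with an identical
#' configuration reproduces every numeric output.
#'
#' @param config a `pipeline_config`
#' @param tasks optional subset of task names to process
#' @param features which feature families to compute
#'   (default both "power" and "network")
#' @param write write CSV outputs to `config$out_dir`
#' @return list: `cohort`, `qc`, `band_power`, `power_stats`, and (when
#'   requested) `network_features`, `network_stats`, plus `manifest`
#' @export
run_all <- function(config = pipeline_config(), tasks = NULL,
                    features = c("power", "network"), write = TRUE) {
  probs <- validate_config(config)
  if (length(probs))
    stop("invalid configuration:\n  ", paste(probs, collapse = "\n  "))
  features <- match.arg(features, several.ok = TRUE)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  out <- list()

  t0 <- tic()
  cohort <- generate_cohort(config$simulation, tasks = tasks)
  timings["simulate"] <- tic() - t0

  t0 <- tic()
  pre <- preprocess_cohort(cohort, config)
  cohort <- pre$cohort
  out$qc <- pre$qc
  timings["preprocess"] <- tic() - t0

  t0 <- tic()
  out$band_power <- cohort_band_power(cohort, config$spectral$window,
                                      config$spectral$overlap,
                                      average_spectra = config$spectral$average_spectra)
  out$power_stats <- run_group_comparison(out$band_power,
                                          alpha = config$stats$alpha)
  timings["power"] <- tic() - t0

  if ("network" %in% features) {
    t0 <- tic()
    out$network_features <- cohort_network_features(
      cohort, bands = config$bands, thresholds = config$sparsity,
      window = config$spectral$window, overlap = config$spectral$overlap)
    out$network_stats <- run_group_comparison(
      out$network_features, alpha = config$stats$alpha,
      fdr_network = config$stats$fdr_network)
    timings["network"] <- tic() - t0
  }
  out$cohort <- cohort
  out$manifest <- list(
    package_version = as.character(utils::packageVersion("eegfc")),
    config_md5 = .config_fingerprint(config),
    seed = config$simulation$seed,
    n_patients = config$simulation$n_patients,
    n_controls = config$simulation$n_controls,
    tasks = names(cohort$subjects[[1]]$recordings),
    sparsity = config$sparsity,
    stage_seconds = as.list(round(timings, 2))
  )
  if (write) .write_run(out, config)
  out
}

# md5 of the serialized configuration (out_dir excluded so the same
# analysis written elsewhere fingerprints identically)
.config_fingerprint <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

.write_run <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) utils::write.csv(
    df, file.path(config$out_dir, name), row.names = FALSE)
  wr(out$cohort$metadata, "metadata.csv")
  segs <- do.call(rbind, lapply(out$cohort$subjects, function(s)
    do.call(rbind, lapply(names(s$recordings), function(task) {
      bs <- s$recordings[[task]]$bad_segments
      if (!nrow(bs)) return(NULL)
      data.frame(subject_id = s$subject_id, task = task,
                 onset_s = bs$onset, duration_s = bs$duration,
                 label = "flatline")
    }))))
  if (is.null(segs))
    segs <- data.frame(subject_id = character(), task = character(),
                       onset_s = numeric(), duration_s = numeric(),
                       label = character())
  wr(segs, "bad_segments.csv")
  wr(out$qc$per_subject, "qc_per_subject.csv")
  wr(out$qc$summary, "qc_summary.csv")
  wr(out$band_power, "band_power.csv")
  wr(out$power_stats, "power_stats.csv")
  if (!is.null(out$network_features)) {
    wr(out$network_features, "network_auc.csv")
    wr(attr(out$network_features, "per_threshold"), "network_per_threshold.csv")
    wr(out$network_stats, "network_stats.csv")
  }
  jsonlite::write_json(out$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(format_stats_report(out$power_stats),
             file.path(config$out_dir, "power_report.txt"))
  invisible(config$out_dir)
}
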