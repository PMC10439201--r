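# Deterministic per-stage seed derived from the top-level seed and a stage
# name, so each stage is independently reproducible. Plain string hash kept
# below 2^31.
stage_seed <- function(seed, stage) {
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Pipeline configuration
#'
#' Collects the analysis parameters with defaults matching standard
#' practice for this kind of normative mapping: resample to 250 Hz,
#' bandpass 1-47.5 Hz, discard the first 30 s of real recordings, a 60-s
#' analysis epoch, Welch with 2-s windows and 50% overlap, the five
#' classical bands, and an sLORETA inverse at an assumed SNR of 3 after
#' common-average re-referencing. Simulation settings default to a
#' 17-control / 22-patient cohort on a 30-sensor toy model.
#'
#' @param fs_target Analysis sampling rate (Hz).
#' @param band Bandpass edges (Hz).
#' @param discard_initial_s Seconds dropped from the start of real
#'   recordings during preprocessing.
#' @param epoch_start_s,epoch_duration_s Analysis epoch (s).
#' @param welch_window_s,welch_overlap Welch settings.
#' @param bands A [band_definition()].
#' @param snr Inverse regularization SNR.
#' @param car Apply a common-average reference before inversion.
#' @param n_sensors,n_rois,sources_per_roi Toy model geometry.
#' @param n_controls,n_patients Cohort sizes.
#' @param jitter_sd,sensor_noise_sd Generator variability settings.
#' @param abnormal_roi,abnormal_band,effect_sd_multiplier Injected patient
#'   abnormality (see [simulate_cohort()]).
#' @param seed Top-level seed; per-stage streams are derived from it.
#' @param out_dir Output directory for [run_pipeline()] artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fs_target = 250, band = c(1, 47.5),
                            discard_initial_s = 30,
                            epoch_start_s = 0, epoch_duration_s = 60,
                            welch_window_s = 2, welch_overlap = 0.5,
                            bands = band_definition(), snr = 3, car = TRUE,
                            n_sensors = 30, n_rois = 20, sources_per_roi = 3,
                            n_controls = 17, n_patients = 22,
                            jitter_sd = 0.10, sensor_noise_sd = 0.05,
                            abnormal_roi = NULL, abnormal_band = "delta",
                            effect_sd_multiplier = 5,
                            seed = 1, out_dir = tempfile("eegnorm_run_")) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

# recordings -> region_band_power tables through the full sensor-space chain
process_recordings <- function(recordings, model, inv, cfg, prefix) {
  lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    rec <- drop_bad_channels(rec)
    if (rec$fs != cfg$fs_target)
      rec <- preprocess(rec, cfg$fs_target, cfg$band, cfg$discard_initial_s)
    if (cfg$car) rec <- common_average_reference(rec)
    src <- apply_inverse(rec, inv)
    rts <- collapse_rois(src, model)
    region_band_power(rts, cfg$epoch_start_s, cfg$epoch_duration_s,
                      cfg$welch_window_s, cfg$welch_overlap, cfg$bands,
                      subject_id = sprintf("%s%03d", prefix, i))
  })
}

#' Run the full normative-mapping pipeline
#'
#' Orchestrates all stages: (simulated or supplied) cohort of sensor
#' recordings, sLORETA inversion with sign-flip region collapse, Welch
#' relative band power, normative map construction with hemispheric-symmetry
#' and epoch-robustness checks, patient z-scoring with the max-across-bands
#' indicator restricted to temporal regions, and ipsi/contra lateralization.
#' All artifacts are written to `config$out_dir` as delimited tables plus a
#' machine-readable JSON run log; the run is deterministic given
#' `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param model Optional `toy_head_model`; built from the config when NULL.
#' @param cohort Optional cohort as returned by [simulate_cohort()]
#'   (`controls`, `patients`, `sides`); simulated from the config when NULL.
#' @return Invisibly, a list with the in-memory results: `model`, `cohort`
#'   truth, `control_tables`, `patient_tables`, `map`, `symmetry_rho`,
#'   `robustness`, `patient_results`, `lateralization`, `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), model = NULL,
                         cohort = NULL) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(model))
    model <- make_toy_head_model(cfg$n_sensors, cfg$n_rois,
                                 cfg$sources_per_roi,
                                 seed = stage_seed(cfg$seed, "model"))
  validate_head_model(model)

  if (is.null(cohort)) {
    abnormal_roi <- cfg$abnormal_roi
    if (is.null(abnormal_roi)) {
      # default: first left temporal region
      abnormal_roi <- model$roi_info$roi[
        model$roi_info$lobe == "temporal" &
          model$roi_info$hemisphere == "L"][1]
    }
    spec <- signal_spec(default_power_profile(model),
                        duration_s = cfg$epoch_duration_s,
                        fs = cfg$fs_target, bands = cfg$bands,
                        sensor_noise_sd = cfg$sensor_noise_sd,
                        jitter_sd = cfg$jitter_sd)
    cohort <- simulate_cohort(model, spec, cfg$n_controls,
                              n_patients = cfg$n_patients,
                              abnormal_roi = abnormal_roi,
                              abnormal_band = cfg$abnormal_band,
                              effect_sd_multiplier = cfg$effect_sd_multiplier,
                              seed = stage_seed(cfg$seed, "cohort"))
  }

  G <- model$leadfield
  if (cfg$car) G <- sweep(G, 2, colMeans(G))  # reference the lead field too
  inv <- build_sloreta_inverse(G, snr = cfg$snr)

  control_tables <- process_recordings(cohort$controls, model, inv, cfg,
                                       "ctrl")
  map <- build_normative_map(control_tables, cfg$bands)
  sym <- hemispheric_symmetry(map, model$roi_info)

  # robustness: two non-overlapping half-epochs of the analysis window
  half <- cfg$epoch_duration_s / 2
  control_rts <- lapply(cohort$controls, function(rec) {
    r <- rec
    r <- drop_bad_channels(r)
    if (r$fs != cfg$fs_target)
      r <- preprocess(r, cfg$fs_target, cfg$band, cfg$discard_initial_s)
    if (cfg$car) r <- common_average_reference(r)
    collapse_rois(apply_inverse(r, inv), model)
  })
  robustness <- epoch_robustness(control_rts, epoch_duration_s = half,
                                 n_epochs = 2,
                                 window_s = cfg$welch_window_s,
                                 overlap_frac = cfg$welch_overlap,
                                 bands = cfg$bands)

  patient_results <- NULL; lat <- NULL
  patient_tables <- NULL
  if (length(cohort$patients) >= 2) {
    patient_tables <- process_recordings(cohort$patients, model, inv, cfg,
                                         "pat")
    patient_results <- lapply(patient_tables, zscore_abnormality, map = map)
    temporal_results <- lapply(patient_results, temporal_subset,
                               roi_info = model$roi_info)
    lat <- lateralize(temporal_results, cohort$sides, model$roi_info)
  }

  paths <- list(
    controls = file.path(cfg$out_dir, "control_band_power.csv"),
    patients = file.path(cfg$out_dir, "patient_band_power.csv"),
    map = file.path(cfg$out_dir, "normative_map.csv"),
    comparisons = file.path(cfg$out_dir, "map_comparisons.csv"),
    abnormality = file.path(cfg$out_dir, "abnormality.csv"),
    lateralization = file.path(cfg$out_dir, "lateralization.csv"),
    log = file.path(cfg$out_dir, "run_log.json")
  )
  write_band_power(control_tables, paths$controls)
  write_map(map, paths$map)
  utils::write.csv(data.frame(
    comparison = c("hemispheric_symmetry", "epoch_robustness_mu",
                   "epoch_robustness_sigma"),
    rho = c(as.numeric(sym), robustness$rho_mu[1], robustness$rho_sigma[1]),
    n_points = c(attr(sym, "n_pairs") * ncol(map$mu),
                 length(map$mu), length(map$mu))
  ), paths$comparisons, row.names = FALSE)
  if (!is.null(patient_results)) {
    write_band_power(patient_tables, paths$patients)
    write_abnormality(patient_results, paths$abnormality)
    write_lateralization(lat, paths$lateralization)
  }
  log <- list(
    package = "eegnorm",
    version = as.character(utils::packageVersion("eegnorm")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    stage_seeds = list(model = stage_seed(cfg$seed, "model"),
                       cohort = stage_seed(cfg$seed, "cohort")),
    config = cfg[setdiff(names(cfg), c("bands", "out_dir"))],
    band_edges = apply(unclass(cfg$bands), 1, identity, simplify = FALSE),
    truth = cohort$truth
  )
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)

  invisible(list(model = model, truth = cohort$truth,
                 control_tables = control_tables,
                 patient_tables = patient_tables, map = map,
                 symmetry_rho = as.numeric(sym), robustness = robustness,
                 patient_results = patient_results, lateralization = lat,
                 paths = paths))
}
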