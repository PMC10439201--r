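#' Canonical five-band definition
#'
#' The five classical EEG frequency bands used throughout the package:
#' delta 1-4, theta 4-8, alpha 8-13, beta 13-30 and gamma 30-47.5 Hz.
#' Bands are contiguous, non-overlapping and span 1-47.5 Hz.
#'
#' @param edges Optional 5 x 2 matrix of (lo, hi) Hz pairs overriding the
#'   defaults; must be contiguous and ordered.
#' @return Object of class `band_definition`: a named list of `(lo, hi)` Hz
#'   pairs with attributes `names` and `range`.
#' @export
band_definition <- function(edges = NULL) {
  nm <- c("delta", "theta", "alpha", "beta", "gamma")
  if (is.null(edges))
    edges <- cbind(c(1, 4, 8, 13, 30), c(4, 8, 13, 30, 47.5))
  edges <- as.matrix(edges)
  if (nrow(edges) != 5 || ncol(edges) != 2) stop("edges must be 5 x 2")
  if (any(edges[, 2] <= edges[, 1])) stop("each band needs hi > lo")
  if (any(abs(edges[-1, 1] - edges[-5, 2]) > 1e-12))
    stop("bands must be contiguous and ordered")
  rownames(edges) <- nm
  colnames(edges) <- c("lo", "hi")
  structure(edges, class = "band_definition")
}

#' Default regional band-power profile for the synthetic generator
#'
#' Produces a target relative-power table (ROI x band, rows summing to 1)
#' with the regional structure typical of healthy resting EEG: alpha power
#' prominent posteriorly, delta elevated anteriorly, on a common baseline of
#' roughly 20% delta, 15% theta, 30% alpha, 25% beta, 10% gamma. The
#' anterior-posterior position of each region's centroid (its y coordinate in
#' the toy geometry, anterior = +y) modulates delta and alpha smoothly.
#'
#' @param model A `toy_head_model`.
#' @param anterior_delta,posterior_alpha Peak additive modulation of the
#'   delta (anterior) and alpha (posterior) fractions (defaults 0.10).
#' @return Matrix (n_rois x 5), rows summing to 1, dimnames set.
#' @export
default_power_profile <- function(model, anterior_delta = 0.10,
                                  posterior_alpha = 0.10) {
  base <- c(delta = 0.20, theta = 0.15, alpha = 0.30, beta = 0.25,
            gamma = 0.10)
  n_rois <- nrow(model$roi_info)
  cy <- vapply(seq_len(n_rois), function(k)
    mean(model$source_positions[model$parcellation == k, 2]), numeric(1))
  # map centroid y to [0, 1]: 1 = most anterior
  a <- (cy - min(cy)) / max(max(cy) - min(cy), 1e-9)
  tab <- matrix(rep(base, each = n_rois), n_rois, 5,
                dimnames = list(model$roi_info$roi, names(base)))
  tab[, "delta"] <- tab[, "delta"] + anterior_delta * a
  tab[, "alpha"] <- tab[, "alpha"] + posterior_alpha * (1 - a)
  tab / rowSums(tab)
}

#' Specification of a synthetic source-space signal
#'
#' @param target_relative_power ROI x band matrix in `[0, 1]`; every row must
#'   sum to 1 (within 1e-9). Row order must match the model's ROI order.
#' @param duration_s Signal duration in seconds.
#' @param fs Sampling rate in Hz; must be at least twice the highest band
#'   edge.
#' @param bands A [band_definition()] (default: the canonical five bands).
#' @param sensor_noise_sd Additive white sensor noise SD used by
#'   [project_to_sensors()] when driven from a cohort simulation.
#' @param jitter_sd Inter-subject lognormal jitter on band powers
#'   (SD of the log), default 0.10.
#' @return Object of class `signal_spec`.
#' @export
signal_spec <- function(target_relative_power, duration_s = 60, fs = 250,
                        bands = band_definition(), sensor_noise_sd = 0.05,
                        jitter_sd = 0.10) {
  tab <- as.matrix(target_relative_power)
  if (any(tab < 0 | tab > 1)) stop("target relative powers must lie in [0,1]")
  if (any(abs(rowSums(tab) - 1) > 1e-9))
    stop("each ROI's target relative powers must sum to 1")
  if (ncol(tab) != nrow(bands)) stop("one column per band required")
  if (fs < 2 * max(bands[, "hi"]))
    stop("fs must be at least twice the highest band edge")
  if (duration_s <= 0) stop("duration_s must be positive")
  structure(list(target_relative_power = tab, duration_s = duration_s,
                 fs = fs, bands = bands, sensor_noise_sd = sensor_noise_sd,
                 jitter_sd = jitter_sd), class = "signal_spec")
}

# Band-limited Gaussian noise with *exactly* the requested variance, built by
# shaping the spectrum of white noise: only Fourier bins inside (lo, hi] are
# retained, so different bands are exactly orthogonal and the realised band
# power fractions equal the targets without filter transients.
band_limited_noise <- function(n, fs, lo, hi, variance) {
  if (variance <= 0) return(numeric(n))
  freqs <- (seq_len(n) - 1) / n * fs
  half <- freqs <= fs / 2
  keep <- which(half & freqs > lo & freqs <= hi)
  if (length(keep) == 0)
    stop("no Fourier bins inside band (", lo, ", ", hi, "] Hz at this length")
  spec <- complex(length.out = n)
  spec[keep] <- complex(real = stats::rnorm(length(keep)),
                        imaginary = stats::rnorm(length(keep)))
  # hermitian mirror for a real signal
  mirror <- n - keep + 2
  mirror_ok <- mirror <= n & mirror != keep
  spec[mirror[mirror_ok]] <- Conj(spec[keep][mirror_ok])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x * sqrt(variance / stats::var(x))
}

#' Simulate band-structured source-space signals
#'
#' Every region receives an independent signal composed of five band-limited
#' noise components whose realised power fractions equal the region's row of
#' `spec$target_relative_power` (components are synthesised in the frequency
#' domain and are exactly orthogonal). All sources within a region share the
#' region's signal, reflecting locally coherent cortical activity. Total
#' variance per source is 1.
#'
#' @param model A `toy_head_model`.
#' @param spec A [signal_spec()]; row order must match the model's ROIs.
#' @param seed Integer seed; output is reproducible given the seed.
#' @return Matrix (n_sources x n_samples) with attribute `fs`.
#' @export
simulate_source_signals <- function(model, spec, seed) {
  stopifnot(inherits(spec, "signal_spec"))
  tab <- spec$target_relative_power
  if (nrow(tab) != nrow(model$roi_info))
    stop("target_relative_power must have one row per ROI")
  set.seed(as.integer(seed))
  n <- round(spec$duration_s * spec$fs)
  n_rois <- nrow(tab)
  roi_sig <- matrix(0, n_rois, n)
  for (k in seq_len(n_rois)) {
    x <- numeric(n)
    for (b in seq_len(nrow(spec$bands))) {
      x <- x + band_limited_noise(n, spec$fs, spec$bands[b, "lo"],
                                  spec$bands[b, "hi"], tab[k, b])
    }
    roi_sig[k, ] <- x
  }
  src <- roi_sig[model$parcellation, , drop = FALSE]
  attr(src, "fs") <- spec$fs
  src
}

#' Project source signals to the sensors
#'
#' Sensor data = leadfield x sources + white Gaussian noise. The projection
#' is exactly linear in the sources; noise is reproducible given the seed.
#'
#' @param model A `toy_head_model`.
#' @param sources Matrix (n_sources x n_samples), e.g. from
#'   [simulate_source_signals()].
#' @param noise_sd Additive sensor noise SD (same units as the projection).
#' @param seed Integer seed for the noise stream.
#' @param fs Sampling rate; taken from `attr(sources, "fs")` if present.
#' @return A [sensor_recording()].
#' @export
project_to_sensors <- function(model, sources, noise_sd = 0, seed = 1,
                               fs = attr(sources, "fs")) {
  if (ncol(model$leadfield) != nrow(sources))
    stop("source count does not match the lead field")
  if (is.null(fs)) stop("sampling rate unknown: pass fs")
  data <- model$leadfield %*% sources
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    data <- data + matrix(stats::rnorm(length(data), sd = noise_sd),
                          nrow(data), ncol(data))
  }
  sensor_recording(data, fs, rownames(model$leadfield))
}

# Delta-method SD of a relative-power cell under row-wise lognormal jitter
# with sdlog s: p_b = g_b t_b / sum_c g_c t_c, Var(p_b) ~ s^2 t_b^2
# (1 - 2 t_b + sum_c t_c^2).
expected_cell_sd <- function(target_row, band_idx, jitter_sd) {
  t_b <- unname(target_row[band_idx])
  jitter_sd * t_b * sqrt(max(1 - 2 * t_b + sum(target_row^2), 0))
}

# Target row with band `band_idx` elevated so the expected relative power
# rises by exactly `delta_p` after renormalisation.
elevate_target_row <- function(target_row, band_idx, delta_p) {
  t_b <- target_row[band_idx]
  if (t_b + delta_p >= 1)
    stop("requested elevation pushes relative power to 1 or beyond")
  d <- delta_p / (1 - t_b - delta_p)
  row <- target_row
  row[band_idx] <- row[band_idx] + d
  row / sum(row)
}

# One subject's jittered target table: independent lognormal factors per
# cell, rows renormalised to sum to 1.
jitter_targets <- function(tab, jitter_sd) {
  if (jitter_sd <= 0) return(tab)
  g <- matrix(stats::rlnorm(length(tab), meanlog = -jitter_sd^2 / 2,
                            sdlog = jitter_sd), nrow(tab), ncol(tab))
  out <- tab * g
  out / rowSums(out)
}

#' Sample subject-level relative band-power tables from the jitter model
#'
#' Draws the generator's inter-subject variability model directly at the
#' band-power level (lognormal multiplicative jitter on the target powers,
#' rows renormalised), without synthesising time series. This is the
#' population model that underlies [simulate_cohort()]; it is useful for
#' fast large-scale calibration studies of the downstream statistics.
#'
#' @param spec A [signal_spec()] (its target table and jitter SD are used).
#' @param n_subjects Number of subjects to draw.
#' @param seed Integer seed.
#' @return List of `region_band_power` matrices (ROI x band), one per subject.
#' @export
sample_band_power <- function(spec, n_subjects, seed) {
  stopifnot(inherits(spec, "signal_spec"))
  set.seed(as.integer(seed))
  lapply(seq_len(n_subjects), function(i) {
    m <- jitter_targets(spec$target_relative_power, spec$jitter_sd)
    class(m) <- c("region_band_power", class(m))
    m
  })
}

#' Simulate a control/patient cohort of sensor recordings
#'
#' Controls are drawn from `control_spec` with inter-subject lognormal jitter
#' on the target band powers. Patients are identical except that the target
#' relative power of `abnormal_band` in the abnormal region is elevated so
#' that the *expected* z-score against the control population (in the sense
#' of the normative z-score, using the jitter-model SD) equals
#' `effect_sd_multiplier`. The abnormality is injected in source space,
#' before sensor mixing, so recovering it exercises the full inverse chain.
#'
#' Each patient carries an epileptogenic side label. By default all patients
#' take the hemisphere of `abnormal_roi`; `patient_sides` can alternate sides,
#' in which case patients labelled with the opposite hemisphere receive the
#' abnormality in the homologue region instead.
#'
#' @param model A `toy_head_model`.
#' @param control_spec A [signal_spec()] for the control population.
#' @param n_controls,n_patients Cohort sizes (either may be 0).
#' @param abnormal_roi ROI label (or index) receiving the abnormality.
#' @param abnormal_band Band name (or index) elevated in patients.
#' @param effect_sd_multiplier Expected z-score of the injected elevation
#'   (>= 0; 0 gives patients exchangeable with controls).
#' @param patient_sides Optional character vector ("L"/"R") of length
#'   `n_patients`; defaults to the hemisphere of `abnormal_roi` for all.
#' @param seed Integer seed; subject-level streams are derived from it.
#' @return List with `controls` and `patients` (lists of
#'   [sensor_recording()]s), `sides` (per patient), `truth` (injected ROI,
#'   band and per-side ROI labels) and the specs used.
#' @export
simulate_cohort <- function(model, control_spec, n_controls,
                            patient_spec = control_spec, n_patients = 0,
                            abnormal_roi = NULL, abnormal_band = NULL,
                            effect_sd_multiplier = 0, patient_sides = NULL,
                            seed = 1) {
  stopifnot(inherits(control_spec, "signal_spec"))
  if (effect_sd_multiplier < 0) stop("effect_sd_multiplier must be >= 0")
  info <- model$roi_info
  roi_idx <- NULL; band_idx <- NULL
  if (n_patients > 0 && effect_sd_multiplier > 0) {
    roi_idx <- if (is.character(abnormal_roi)) match(abnormal_roi, info$roi)
               else as.integer(abnormal_roi)
    if (is.na(roi_idx) || roi_idx < 1 || roi_idx > nrow(info))
      stop("unknown abnormal_roi: ", abnormal_roi)
    band_names <- rownames(control_spec$bands)
    band_idx <- if (is.character(abnormal_band))
      match(abnormal_band, band_names) else as.integer(abnormal_band)
    if (is.na(band_idx) || band_idx < 1 || band_idx > length(band_names))
      stop("unknown abnormal_band: ", abnormal_band)
  }
  if (is.null(patient_sides)) {
    side <- if (!is.null(roi_idx)) info$hemisphere[roi_idx] else "L"
    patient_sides <- rep(side, n_patients)
  }
  if (n_patients > 0 && length(patient_sides) != n_patients)
    stop("patient_sides must have one entry per patient")

  # homologue of the abnormal ROI, for patients lateralised to the other side
  mate_idx <- NA_integer_
  if (!is.null(roi_idx) && !is.na(info$pair[roi_idx])) {
    mate_idx <- which(info$pair == info$pair[roi_idx] &
                        seq_len(nrow(info)) != roi_idx)
  }

  one_subject <- function(spec, tab, sub_seed) {
    sp <- spec
    sp$target_relative_power <- tab
    src <- simulate_source_signals(model, sp, seed = sub_seed)
    project_to_sensors(model, src, noise_sd = spec$sensor_noise_sd,
                       seed = sub_seed + 1L)
  }

  set.seed(as.integer(seed))
  subject_seeds <- sample.int(2^30, n_controls + n_patients + 1) # jitter uses
  # the stream below; per-subject synthesis uses these derived seeds.

  controls <- lapply(seq_len(n_controls), function(i) {
    tab <- jitter_targets(control_spec$target_relative_power,
                          control_spec$jitter_sd)
    one_subject(control_spec, tab, subject_seeds[i])
  })

  patients <- lapply(seq_len(n_patients), function(i) {
    tab <- jitter_targets(patient_spec$target_relative_power,
                          patient_spec$jitter_sd)
    target_idx <- roi_idx
    if (!is.null(roi_idx) && patient_sides[i] != info$hemisphere[roi_idx]) {
      if (is.na(mate_idx))
        stop("abnormal_roi has no homologue; cannot lateralise to the other side")
      target_idx <- mate_idx
    }
    if (!is.null(roi_idx) && effect_sd_multiplier > 0) {
      row0 <- patient_spec$target_relative_power[target_idx, ]
      sdc <- expected_cell_sd(row0, band_idx, control_spec$jitter_sd)
      tab[target_idx, ] <- elevate_target_row(
        tab[target_idx, ], band_idx, effect_sd_multiplier * sdc)
    }
    one_subject(patient_spec, tab, subject_seeds[n_controls + i])
  })

  list(controls = controls, patients = patients, sides = patient_sides,
       truth = list(
         abnormal_roi = if (!is.null(roi_idx)) info$roi[roi_idx] else NA,
         homologue_roi = if (!is.na(mate_idx)) info$roi[mate_idx] else NA,
         abnormal_band = if (!is.null(band_idx))
           rownames(control_spec$bands)[band_idx] else NA,
         effect_sd_multiplier = effect_sd_multiplier),
       control_spec = control_spec, patient_spec = patient_spec)
}
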