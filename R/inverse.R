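#' Preprocess a sensor recording
#'
#' Applies the standard resting-state preparation: discard the initial
#' settling segment, zero-phase bandpass filter, and downsample. Defaults
#' follow common clinical practice: resample to 250 Hz, bandpass 1-47.5 Hz
#' (staying below mains frequency), and drop the first 30 s.
#'
#' Downsampling is staged anti-aliased decimation (an 8th-order Butterworth
#' low-pass at 80% of each stage's output Nyquist, applied forward and
#' backward, then subsampling; stage factors are kept small for numerical
#' stability). The bandpass then runs at the target rate as a zero-phase
#' (forward-backward) 4th-order Butterworth high-pass at `band[1]` cascaded
#' with a 10th-order Butterworth low-pass at `band[2]`; the low-pass order
#' is chosen so mains frequency (60 Hz, and a fortiori 50 Hz) is attenuated
#' by more than 40 dB. `target_fs` must divide `rec$fs`.
#'
#' @param rec A [sensor_recording()].
#' @param target_fs Output sampling rate in Hz (default 250).
#' @param band Passband `(lo, hi)` in Hz (default `c(1, 47.5)`); must lie
#'   within `(0, target_fs / 2)`.
#' @param discard_initial_s Seconds removed from the start (default 30).
#' @return A [sensor_recording()] at `target_fs`.
#' @export
preprocess <- function(rec, target_fs = 250, band = c(1, 47.5),
                       discard_initial_s = 30) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (target_fs > rec$fs) stop("target_fs must not exceed the recording fs")
  if (band[1] <= 0 || band[2] >= target_fs / 2)
    stop("band must lie within (0, target_fs/2)")
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9)
    stop("target_fs must divide the recording sampling rate")
  factor <- round(factor)
  n_skip <- round(discard_initial_s * rec$fs)
  if (n_skip >= ncol(rec$data))
    stop("recording shorter than discard_initial_s (",
         ncol(rec$data) / rec$fs, " s < ", discard_initial_s, " s)")
  data <- rec$data[, (n_skip + 1):ncol(rec$data), drop = FALSE]

  # staged decimation: factors <= 10 keep the anti-alias IIR well conditioned
  fs_cur <- rec$fs
  while (factor > 1) {
    divisors <- which(factor %% seq_len(min(factor, 10)) == 0)
    q <- max(divisors)
    if (q == 1) q <- factor  # prime factor > 10: single stage

    aa <- signal::butter(8, 0.8 / q, type = "low")
    data <- t(apply(data, 1, function(x) signal::filtfilt(aa, x - mean(x))))
    data <- data[, seq(1, ncol(data), by = q), drop = FALSE]
    fs_cur <- fs_cur / q
    factor <- factor / q
  }

  hp <- signal::butter(4, band[1] * 2 / fs_cur, type = "high")
  lp <- signal::butter(10, band[2] * 2 / fs_cur, type = "low")
  filtered <- t(apply(data, 1, function(x)
    signal::filtfilt(lp, signal::filtfilt(hp, x - mean(x)))))
  sensor_recording(filtered, target_fs, rec$channel_labels,
                   rec$bad_channels)
}

#' Build an sLORETA inverse operator
#'
#' Standardized minimum-norm inverse for orientation-constrained sources.
#' The minimum-norm kernel is `M = G' (G G' + lambda C)^-1`, with the
#' regularization set from an assumed signal-to-noise ratio as
#' `lambda = trace(G G') / (n_sensors * snr^2)` (so doubling the SNR divides
#' lambda by four; `snr = Inf` gives the unregularized kernel). Each source's
#' estimate is then standardized by the square root of the corresponding
#' diagonal element of the resolution matrix `R = M G`: row `i` of the kernel
#' is divided by `sqrt(R[i, i])`. On an exact noiseless single-source model
#' this standardization yields zero localization error.
#'
#' @param model A `toy_head_model`, or a bare lead-field matrix
#'   (sensors x sources).
#' @param noise_cov Sensor noise covariance `C` (symmetric positive
#'   semidefinite); identity by default.
#' @param snr Assumed amplitude SNR (> 0, possibly `Inf`; default 3, a
#'   conventional resting-EEG choice).
#' @return Object of class `inverse_operator`: `kernel`
#'   (n_sources x n_sensors), `lambda`, `snr`, `noise_cov_id`.
#' @export
build_sloreta_inverse <- function(model, noise_cov = NULL, snr = 3) {
  G <- if (inherits(model, "toy_head_model")) model$leadfield else
    as.matrix(model)
  if (!is.numeric(snr) || length(snr) != 1 || snr <= 0)
    stop("snr must be a single positive number")
  n_sensors <- nrow(G)
  noise_cov_id <- "identity"
  if (is.null(noise_cov)) noise_cov <- diag(n_sensors)
  else {
    noise_cov <- as.matrix(noise_cov)
    if (!isSymmetric(noise_cov, tol = 1e-8))
      stop("noise_cov must be symmetric")
    if (min(eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-8 * max(abs(noise_cov)))
      stop("noise_cov must be positive semidefinite")
    noise_cov_id <- "user"
  }
  gram <- tcrossprod(G)
  lambda <- if (is.infinite(snr)) 0 else sum(diag(gram)) / (n_sensors * snr^2)
  A <- gram + lambda * noise_cov
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("regularized Gram matrix is singular (lambda = ", signif(lambda, 4),
         ", rank ", qr(A)$rank, " of ", n_sensors,
         "); increase lambda or check the lead field"))
  M <- crossprod(G, Ainv)
  # diag(R) with R = M G, without forming R
  r_diag <- rowSums(M * t(G))
  if (any(r_diag <= 0))
    stop("non-positive resolution variance encountered; ",
         "the lead field may contain a null source")
  kernel <- M / sqrt(r_diag)
  structure(list(kernel = kernel, lambda = lambda, snr = snr,
                 noise_cov_id = noise_cov_id),
            class = "inverse_operator")
}

#' Apply an inverse operator to a sensor recording
#'
#' Source estimates = kernel x sensor data; exactly linear and
#' deterministic. Bad channels must already have been dropped from both the
#' recording and the lead field used to build the operator.
#'
#' @param rec A [sensor_recording()] (or a bare channels x samples matrix).
#' @param inv An [build_sloreta_inverse()] operator.
#' @return Matrix (n_sources x n_samples) of standardized source estimates,
#'   with attribute `fs` when available.
#' @export
apply_inverse <- function(rec, inv) {
  stopifnot(inherits(inv, "inverse_operator"))
  data <- if (inherits(rec, "sensor_recording")) rec$data else as.matrix(rec)
  if (ncol(inv$kernel) != nrow(data))
    stop("channel count (", nrow(data), ") does not match the inverse kernel (",
         ncol(inv$kernel), " sensors)")
  src <- inv$kernel %*% data
  if (inherits(rec, "sensor_recording")) attr(src, "fs") <- rec$fs
  src
}

#' Collapse source time series to one series per region
#'
#' Orientation-constrained estimates on opposite sulcal walls point in
#' opposite directions, so naive averaging within a region cancels signal.
#' Each source is therefore sign-flipped to align with the region's dominant
#' component before averaging: the flips are the signs of the sources'
#' loadings on the first principal component of the region's source matrix
#' (a zero loading keeps +1). The collapsed series is invariant, up to a
#' single global sign per region, to flipping the sign of any individual
#' source's input; its correlation with the dominant component is positive
#' by construction, which fixes the output reproducibly.
#'
#' @param src Matrix (n_sources x n_samples), e.g. from [apply_inverse()].
#' @param model A `toy_head_model`, or a list with `parcellation` (integer
#'   ROI per source) and `roi_info$roi` labels.
#' @param fs Sampling rate; taken from `attr(src, "fs")` if present.
#' @return Object of class `region_ts`: `data` (n_rois x n_samples), `fs`,
#'   `roi_labels`, and `flip_signs` (the per-source signs used).
#' @export
collapse_rois <- function(src, model, fs = attr(src, "fs")) {
  parcellation <- model$parcellation
  roi_labels <- model$roi_info$roi
  if (length(parcellation) != nrow(src))
    stop("parcellation length does not match the number of sources")
  n_rois <- length(roi_labels)
  counts <- tabulate(parcellation, n_rois)
  if (any(counts == 0))
    stop("empty ROI(s): ", paste(roi_labels[counts == 0], collapse = ", "))
  out <- matrix(0, n_rois, ncol(src))
  flips <- rep(1, nrow(src))
  for (k in seq_len(n_rois)) {
    rows <- which(parcellation == k)
    block <- src[rows, , drop = FALSE]
    if (length(rows) == 1) {
      out[k, ] <- block
      next
    }
    sv <- svd(block, nu = 1, nv = 1)
    s <- sign(sv$u[, 1])
    s[s == 0] <- 1
    flips[rows] <- s
    collapsed <- colMeans(block * s)
    # align the region series with its dominant temporal component
    if (sum(collapsed * sv$v[, 1]) < 0) {
      collapsed <- -collapsed
      flips[rows] <- -flips[rows]
    }
    out[k, ] <- collapsed
  }
  rownames(out) <- roi_labels
  structure(list(data = out, fs = fs, roi_labels = roi_labels,
                 flip_signs = flips), class = "region_ts")
}

#' @export
print.region_ts <- function(x, ...) {
  cat(sprintf("region_ts: %d ROIs x %d samples @ %s Hz\n",
              nrow(x$data), ncol(x$data),
              if (is.null(x$fs)) "?" else format(x$fs)))
  invisible(x)
}
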