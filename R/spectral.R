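#' Select a contiguous epoch from a region time series
#'
#' @param rts A `region_ts` (from [collapse_rois()]) or a
#'   [sensor_recording()].
#' @param start_s Epoch start in seconds from the beginning of the series.
#' @param duration_s Epoch length in seconds (default 60; 30-s epochs are
#'   used for robustness analyses).
#' @return Object of the same class, restricted to the epoch.
#' @export
select_epoch <- function(rts, start_s = 0, duration_s = 60) {
  fs <- rts$fs
  n <- ncol(rts$data)
  i0 <- round(start_s * fs) + 1
  i1 <- round((start_s + duration_s) * fs)
  if (start_s < 0 || duration_s <= 0) stop("epoch bounds must be nonnegative")
  if (i1 > n)
    stop("epoch [", start_s, ", ", start_s + duration_s,
         ") s exceeds the recording (", n / fs, " s)")
  out <- rts
  out$data <- rts$data[, i0:i1, drop = FALSE]
  out
}

#' Welch power spectral density of region time series
#'
#' Averaged modified periodograms: the signal is split into overlapping
#' segments (default 2 s with 50% overlap), each segment is mean-detrended,
#' Hann-tapered and Fourier transformed, and the one-sided density is
#' normalised by `fs * sum(w^2)` so that integrating the PSD over frequency
#' recovers the signal variance (Parseval). Frequency resolution is
#' `1 / window_s` (0.5 Hz at the defaults).
#'
#' @param rts A `region_ts`, [sensor_recording()], or bare rows x samples
#'   matrix with an `fs` attribute.
#' @param window_s Segment length in seconds (default 2).
#' @param overlap_frac Fractional overlap between segments in `[0, 1)`
#'   (default 0.5).
#' @param fs Sampling rate override.
#' @return Object of class `psd_table`: `psd` (rows x frequency bins,
#'   units^2/Hz), `freq` (Hz), `fs`, `labels`.
#' @export
welch_psd <- function(rts, window_s = 2, overlap_frac = 0.5, fs = NULL) {
  if (is.list(rts)) {
    data <- rts$data
    if (is.null(fs)) fs <- rts$fs
    labels <- if (!is.null(rts$roi_labels)) rts$roi_labels else
      rts$channel_labels
  } else {
    data <- as.matrix(rts)
    if (is.null(fs)) fs <- attr(rts, "fs")
    labels <- rownames(data)
  }
  if (is.null(fs)) stop("sampling rate unknown: pass fs")
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must lie in [0, 1)")
  nper <- round(window_s * fs)
  if (nper < 2) stop("window too short: fewer than 2 samples")
  if (ncol(data) < nper)
    stop("signal shorter than one window (", ncol(data), " < ", nper,
         " samples)")
  step <- max(1, round(nper * (1 - overlap_frac)))
  starts <- seq(1, ncol(data) - nper + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / nper)   # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  n_freq <- nper %/% 2 + 1
  freq <- (seq_len(n_freq) - 1) * fs / nper

  psd <- matrix(0, nrow(data), n_freq)
  for (s0 in starts) {
    seg <- data[, s0:(s0 + nper - 1), drop = FALSE]
    seg <- seg - rowMeans(seg)
    ft <- t(stats::mvfft(t(seg * rep(w, each = nrow(seg)))))
    psd <- psd + Mod(ft[, seq_len(n_freq), drop = FALSE])^2 * scale
  }
  psd <- psd / length(starts)
  # one-sided: double everything except DC and (for even nper) Nyquist
  dbl <- rep(2, n_freq); dbl[1] <- 1
  if (nper %% 2 == 0) dbl[n_freq] <- 1
  psd <- sweep(psd, 2, dbl, "*")
  rownames(psd) <- labels
  structure(list(psd = psd, freq = freq, fs = fs, labels = labels),
            class = "psd_table")
}

# Riemann sum of the PSD over the half-open band (lo, hi]: every frequency
# bin belongs to exactly one band (shared edges 4, 8, 13, 30 Hz count once,
# toward the lower band), so the five band powers partition the total power
# exactly. The same convention is used by the synthetic generator's
# frequency-domain synthesis, making the two ends of the pipeline agree.
band_power_sum <- function(freq, y, lo, hi) {
  if (lo < freq[1] - 1e-9 || hi > freq[length(freq)] + 1e-9)
    stop("band (", lo, ", ", hi, "] Hz outside the PSD frequency axis")
  df <- freq[2] - freq[1]
  sum(y[freq > lo & freq <= hi]) * df
}

#' Relative band power from a PSD table
#'
#' Integrates the PSD over each band (Riemann sum over the half-open bin
#' range `(lo, hi]`, so every bin contributes to exactly one band and the
#' five band powers partition the total 1-47.5 Hz power) and divides by the
#' total across the five bands. Rows therefore sum to 1 and the result is
#' invariant to rescaling any region's signal.
#'
#' @param psd A `psd_table` from [welch_psd()].
#' @param bands A [band_definition()].
#' @param subject_id Optional subject identifier stored as an attribute.
#' @return Object of class `region_band_power`: a ROI x band matrix of
#'   relative powers in `[0, 1]` with rows summing to 1.
#' @export
relative_band_power <- function(psd, bands = band_definition(),
                                subject_id = NULL) {
  stopifnot(inherits(psd, "psd_table"))
  n_rows <- nrow(psd$psd)
  bp <- matrix(0, n_rows, nrow(bands),
               dimnames = list(psd$labels, rownames(bands)))
  for (b in seq_len(nrow(bands))) {
    for (i in seq_len(n_rows)) {
      bp[i, b] <- band_power_sum(psd$freq, psd$psd[i, ], bands[b, "lo"],
                                 bands[b, "hi"])
    }
  }
  tot <- rowSums(bp)
  if (any(tot <= 0))
    stop("zero total band power in region(s): ",
         paste(psd$labels[tot <= 0], collapse = ", "))
  rel <- bp / tot
  attr(rel, "subject_id") <- subject_id
  attr(rel, "fs") <- psd$fs
  class(rel) <- c("region_band_power", class(rel))
  rel
}

#' Region x band relative power for one recording in one call
#'
#' Convenience wrapper: epoch selection, Welch PSD and band normalisation.
#'
#' @param rts A `region_ts`.
#' @param start_s,duration_s Epoch bounds (defaults 0 and 60 s).
#' @param window_s,overlap_frac Welch settings (defaults 2 s, 0.5).
#' @param bands A [band_definition()].
#' @param subject_id Optional subject identifier.
#' @return A `region_band_power` matrix.
#' @export
region_band_power <- function(rts, start_s = 0, duration_s = 60,
                              window_s = 2, overlap_frac = 0.5,
                              bands = band_definition(), subject_id = NULL) {
  ep <- select_epoch(rts, start_s, duration_s)
  relative_band_power(welch_psd(ep, window_s, overlap_frac), bands,
                      subject_id)
}
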