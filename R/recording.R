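#' Sensor-space EEG recording
#'
#' Lightweight container for a multichannel recording: a channels x samples
#' matrix (microvolts by convention), its sampling rate and channel labels,
#' and an optional set of bad-channel labels.
#'
#' @param data Numeric matrix, channels x samples; all values finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector, one label per channel; defaults to
#'   the matrix rownames or auto-generated labels.
#' @param bad_channels Labels of channels to be excluded from analysis
#'   (must be a subset of `channel_labels`).
#' @return Object of class `sensor_recording` with fields `data`, `fs`,
#'   `channel_labels`, `bad_channels`.
#' @export
sensor_recording <- function(data, fs, channel_labels = NULL,
                             bad_channels = character(0)) {
  data <- as.matrix(data)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  if (!all(is.finite(data))) stop("recording contains non-finite samples")
  if (is.null(channel_labels)) channel_labels <- rownames(data)
  if (is.null(channel_labels))
    channel_labels <- paste0("EEG", sprintf("%03d", seq_len(nrow(data))))
  if (length(channel_labels) != nrow(data))
    stop("one channel label per data row required")
  if (!all(bad_channels %in% channel_labels))
    stop("bad_channels must be a subset of channel_labels")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 bad_channels = bad_channels), class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("sensor_recording: %d channels x %d samples @ %g Hz (%.1f s)",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (length(x$bad_channels))
    cat(sprintf(", %d bad", length(x$bad_channels)))
  cat("\n")
  invisible(x)
}

#' Drop bad channels from a recording
#'
#' Channels listed in `rec$bad_channels` (plus any extra labels supplied) are
#' removed outright rather than interpolated.
#'
#' @param rec A [sensor_recording()].
#' @param extra Additional channel labels to drop.
#' @return A [sensor_recording()] without the dropped channels.
#' @export
drop_bad_channels <- function(rec, extra = character(0)) {
  bad <- union(rec$bad_channels, extra)
  keep <- !(rec$channel_labels %in% bad)
  if (!any(keep)) stop("dropping bad channels would leave no data")
  sensor_recording(rec$data[keep, , drop = FALSE], rec$fs,
                   rec$channel_labels[keep])
}

#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous mean across the retained channels from every
#' channel. Applied after bad-channel removal and before source inversion.
#'
#' @param rec A [sensor_recording()].
#' @return The re-referenced [sensor_recording()].
#' @export
common_average_reference <- function(rec) {
  avg <- colMeans(rec$data)
  sensor_recording(sweep(rec$data, 2, avg, "-"), rec$fs, rec$channel_labels,
                   rec$bad_channels)
}

# ---------------------------------------------------------------------------
# EDF (European Data Format, 16-bit): fixed-layout ASCII header + int16
# little-endian payload. One data record holding the whole signal is written,
# which EDF permits and keeps the writer exactly invertible up to 16-bit
# quantization.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as EDF
#'
#' Standard 16-bit EDF with channel labels and sampling rate in the header.
#' Each channel is scaled to its own physical range, so the round trip
#' through [read_edf()] is exact up to 16-bit quantization of that range.
#'
#' @param rec A [sensor_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  data <- rec$data
  ns <- nrow(data)
  nsamp <- ncol(data)
  dig_min <- -32767; dig_max <- 32767
  phys_max <- apply(abs(data), 1, max)
  phys_max[phys_max == 0] <- 1
  phys_min <- -phys_max

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, eos = NULL)
  wr("0", 8)                                   # version
  wr("X X X X", 80)                            # patient id
  wr("Startdate X X X X", 80)                  # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)         # date, time
  wr(256 * (ns + 1), 8)                        # header bytes
  wr("", 44)
  wr(1, 8)                                     # one data record
  wr(format(nsamp / rec$fs, digits = 8), 8)    # record duration (s)
  wr(ns, 4)
  for (lab in rec$channel_labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)            # transducer
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(phys_min[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(format(phys_max[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)            # prefiltering
  for (i in seq_len(ns)) wr(nsamp, 8)          # samples per record
  for (i in seq_len(ns)) wr("", 32)
  for (i in seq_len(ns)) {
    dig <- round((data[i, ] - phys_min[i]) / (phys_max[i] - phys_min[i]) *
                   (dig_max - dig_min) + dig_min)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Parses the fixed-layout EDF header and the 16-bit payload, rescaling each
#' channel to its physical range. Annotation channels are not supported.
#'
#' @param path Path to an EDF file.
#' @return A [sensor_recording()] in the file's physical units.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    x <- readChar(con, width, useBytes = TRUE)
    if (nchar(x, type = "bytes") < width)
      stop("malformed EDF header in ", path, ": truncated at byte ",
           seek(con))
    trimws(x)
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_records <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_records) || n_records < 1)
    stop("malformed EDF header in ", path, ": bad signal/record counts")
  if (header_bytes != 256 * (ns + 1))
    stop("malformed EDF header in ", path, ": header size field inconsistent")
  field <- function(width) vapply(seq_len(ns), function(i) rd(width),
                                  character(1))
  labels <- field(16); field(80); field(8)
  phys_min <- as.numeric(field(8)); phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8)); dig_max <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8))
  field(32)
  if (any(is.na(phys_min) | is.na(phys_max) | is.na(spr)))
    stop("malformed EDF header in ", path, ": bad signal fields")

  chans <- vector("list", ns)
  for (i in seq_len(ns)) chans[[i]] <- numeric(n_records * spr[i])
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      if (length(raw) < spr[i])
        stop("truncated EDF payload in ", path, ": record ", r, ", signal ",
             i, " (expected ", spr[i], " samples, got ", length(raw), ")")
      chans[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (raw - dig_min[i]) / (dig_max[i] - dig_min[i]) *
        (phys_max[i] - phys_min[i]) + phys_min[i]
    }
  }
  fs <- spr[1] / rec_dur
  data <- do.call(rbind, chans)
  sensor_recording(data, fs, labels)
}

# ---------------------------------------------------------------------------
# BrainVision: INI-style .vhdr text header + raw binary .eeg payload
# (.vmrk markers are not needed beyond segment bounds and are ignored).

parse_vhdr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("Brain Vision Data Exchange Header",
                               lines[1], ignore.case = TRUE))
    stop("malformed BrainVision header in ", path, ": missing identification line")
  section <- ""
  kv <- list(); channels <- list()
  for (ln in lines[-1]) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- tolower(gsub("[][]", "", ln))
      next
    }
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(m) != 3) next
    key <- trimws(m[2]); val <- trimws(m[3])
    if (section == "channel infos") channels[[key]] <- val
    else kv[[paste(section, tolower(key))]] <- val
  }
  list(kv = kv, channels = channels)
}

#' Read a BrainVision recording
#'
#' Parses the `.vhdr` text header and the binary `.eeg` payload
#' (`IEEE_FLOAT_32` or `INT_16`, multiplexed or vectorized orientation).
#' Channel resolutions from the header are applied, yielding microvolts.
#'
#' @param path Path to the `.vhdr` header file.
#' @return A [sensor_recording()].
#' @export
read_brainvision <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  h <- parse_vhdr(path)
  kv <- h$kv
  need <- function(key) {
    v <- kv[[key]]
    if (is.null(v)) stop("malformed BrainVision header in ", path,
                         ": missing ", key)
    v
  }
  if (toupper(need("common infos dataformat")) != "BINARY")
    stop("only BINARY BrainVision data is supported")
  n_chan <- as.integer(need("common infos numberofchannels"))
  fs <- 1e6 / as.numeric(need("common infos samplinginterval"))
  orientation <- toupper(need("common infos orientation"))
  fmt <- toupper(need("binary infos binaryformat"))
  data_file <- file.path(dirname(path), need("common infos datafile"))
  if (!file.exists(data_file)) stop("no such data file: ", data_file)

  labels <- character(n_chan); resolution <- rep(1, n_chan)
  for (i in seq_len(n_chan)) {
    entry <- h$channels[[paste0("Ch", i)]]
    if (is.null(entry)) stop("malformed BrainVision header in ", path,
                             ": missing Ch", i)
    parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
    labels[i] <- trimws(parts[1])
    if (length(parts) >= 3 && nzchar(trimws(parts[3])))
      resolution[i] <- as.numeric(parts[3])
  }

  sz <- if (fmt == "IEEE_FLOAT_32") 4L else if (fmt == "INT_16") 2L else
    stop("unsupported BinaryFormat: ", fmt)
  n_bytes <- file.info(data_file)$size
  n_values <- n_bytes %/% sz
  if (n_values %% n_chan != 0)
    stop("truncated BrainVision payload in ", data_file, ": ", n_bytes,
         " bytes is not a whole number of ", n_chan, "-channel samples")
  con <- file(data_file, "rb")
  on.exit(close(con))
  raw <- if (fmt == "IEEE_FLOAT_32")
    readBin(con, "numeric", n = n_values, size = 4, endian = "little")
  else
    readBin(con, "integer", n = n_values, size = 2, signed = TRUE,
            endian = "little")
  n_samp <- n_values %/% n_chan
  data <- if (orientation == "MULTIPLEXED") matrix(raw, n_chan, n_samp)
          else t(matrix(raw, n_samp, n_chan))
  data <- data * resolution
  sensor_recording(data, fs, labels)
}

#' Write a recording in BrainVision format
#'
#' Emits a `.vhdr` text header, a minimal `.vmrk` marker file and a binary
#' `.eeg` payload (`IEEE_FLOAT_32`, multiplexed), readable by
#' [read_brainvision()] and standard tooling.
#'
#' @param rec A [sensor_recording()].
#' @param path Path of the `.vhdr` file to write (companion `.eeg`/`.vmrk`
#'   files are placed alongside).
#' @return `path`, invisibly.
#' @export
write_brainvision <- function(rec, path) {
  stem <- sub("\\.vhdr$", "", path)
  eeg_file <- paste0(stem, ".eeg"); vmrk_file <- paste0(stem, ".vmrk")
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", basename(eeg_file)),
    paste0("MarkerFile=", basename(vmrk_file)),
    "DataFormat=BINARY",
    "Orientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$fs, digits = 12)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    paste0("Ch", seq_along(rec$channel_labels), "=",
           rec$channel_labels, ",,1,µV")
  )
  writeLines(hdr, path)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Marker Infos]",
               "Mk1=New Segment,,1,1,0,00000000000000000000"), vmrk_file)
  con <- file(eeg_file, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a sensor recording from disk
#'
#' Dispatches on format: EDF or BrainVision (the `.vhdr` header file).
#'
#' @param path File path (`.edf` or `.vhdr`).
#' @param format `"edf"`, `"brainvision"`, or `"auto"` (by extension).
#' @return A [sensor_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "brainvision")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vhdr$", path, ignore.case = TRUE)) "brainvision"
              else "edf"
  }
  switch(format, edf = read_edf(path), brainvision = read_brainvision(path))
}
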