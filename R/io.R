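# Delimited-table interchange: long-format UTF-8 CSV with a header row,
# diffable and language-neutral.

#' Write / read relative band-power tables
#'
#' Long format with columns `subject`, `roi`, `band`, `rel_power`. One file
#' may hold many subjects.
#'
#' @param tables A single `region_band_power` matrix or a (optionally named)
#'   list of them.
#' @param path CSV file path.
#' @return `write_band_power`: `path` invisibly. `read_band_power`: a named
#'   list of `region_band_power` matrices.
#' @export
write_band_power <- function(tables, path) {
  if (inherits(tables, "region_band_power")) tables <- list(tables)
  ids <- names(tables)
  if (is.null(ids)) ids <- rep("", length(tables))
  rows <- lapply(seq_along(tables), function(i) {
    tab <- tables[[i]]
    id <- ids[i]
    if (!nzchar(id)) {
      id <- attr(tab, "subject_id")
      if (is.null(id)) id <- sprintf("sub%03d", i)
    }
    data.frame(subject = id,
               roi = rep(rownames(tab), times = ncol(tab)),
               band = rep(colnames(tab), each = nrow(tab)),
               rel_power = as.vector(unclass(tab)),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_band_power
#' @export
read_band_power <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "roi", "band", "rel_power")
  if (!all(need %in% names(df)))
    stop("band-power table must have columns: ", paste(need, collapse = ", "))
  rois <- unique(df$roi); bands <- unique(df$band)
  out <- lapply(split(df, factor(df$subject, unique(df$subject))),
                function(d) {
    m <- matrix(NA_real_, length(rois), length(bands),
                dimnames = list(rois, bands))
    m[cbind(match(d$roi, rois), match(d$band, bands))] <- d$rel_power
    if (anyNA(m)) stop("incomplete ROI x band grid for subject ",
                       d$subject[1])
    class(m) <- c("region_band_power", class(m))
    m
  })
  out
}

#' Write / read a normative map
#'
#' Long format with columns `roi`, `band`, `lo_hz`, `hi_hz`, `mean`, `sd`,
#' `n`, `parcellation`; the round trip restores mu, sigma, subject count,
#' band edges and parcellation id exactly. `read_map` also ingests external
#' map tables (e.g. published normative maps) whose columns are named
#' differently, via the `columns` mapping.
#'
#' @param map A `normative_map`.
#' @param path CSV file path.
#' @param columns Named character vector mapping the canonical names
#'   `roi`, `band`, `mean`, `sd` (and optionally `n`) to the file's column
#'   names, for externally produced tables.
#' @param parcellation_id Override for tables that do not carry one.
#' @return `write_map`: `path` invisibly. `read_map`: a `normative_map`.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "normative_map"))
  edges <- map$bands
  df <- data.frame(
    roi = rep(rownames(map$mu), times = ncol(map$mu)),
    band = rep(colnames(map$mu), each = nrow(map$mu)),
    lo_hz = rep(edges[, "lo"], each = nrow(map$mu)),
    hi_hz = rep(edges[, "hi"], each = nrow(map$mu)),
    mean = as.vector(map$mu),
    sd = as.vector(map$sigma),
    n = map$n_subjects,
    parcellation = map$parcellation_id,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path, columns = NULL, parcellation_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  canon <- c(roi = "roi", band = "band", mean = "mean", sd = "sd", n = "n")
  if (!is.null(columns)) canon[names(columns)] <- columns
  missing_cols <- setdiff(canon[c("roi", "band", "mean", "sd")], names(df))
  if (length(missing_cols))
    stop("map table is missing column(s): ",
         paste(missing_cols, collapse = ", "),
         " (use `columns` to map external names)")
  rois <- unique(df[[canon["roi"]]])
  bands <- unique(df[[canon["band"]]])
  shape <- function(col) {
    m <- matrix(NA_real_, length(rois), length(bands),
                dimnames = list(rois, bands))
    m[cbind(match(df[[canon["roi"]]], rois),
            match(df[[canon["band"]]], bands))] <- df[[col]]
    if (anyNA(m)) stop("incomplete ROI x band grid in ", path)
    m
  }
  mu <- shape(canon["mean"]); sigma <- shape(canon["sd"])
  if (any(sigma <= 0))
    stop("invalid map: ", sum(sigma <= 0), " cell(s) with sd <= 0")
  n <- if (canon["n"] %in% names(df)) df[[canon["n"]]][1] else NA_integer_
  bands_def <- if (all(c("lo_hz", "hi_hz") %in% names(df))) {
    first <- !duplicated(df[[canon["band"]]])
    band_definition(cbind(df$lo_hz[first], df$hi_hz[first]))
  } else band_definition()
  if (is.null(parcellation_id))
    parcellation_id <- if ("parcellation" %in% names(df))
      df$parcellation[1] else "unknown"
  structure(list(mu = mu, sigma = sigma, n_subjects = n, bands = bands_def,
                 parcellation_id = parcellation_id),
            class = "normative_map")
}

#' Write / read a lead-field matrix as a delimited table
#'
#' Sensors x sources CSV; the first column holds channel labels.
#'
#' @param leadfield Numeric matrix (or `toy_head_model`).
#' @param path CSV file path.
#' @return `write_leadfield`: `path` invisibly. `read_leadfield`: the matrix
#'   with channel labels as rownames.
#' @export
write_leadfield <- function(leadfield, path) {
  if (inherits(leadfield, "toy_head_model")) leadfield <- leadfield$leadfield
  df <- data.frame(channel = rownames(leadfield), leadfield,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_leadfield
#' @export
read_leadfield <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "channel") stop("lead-field table must start with a 'channel' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(df$channel, NULL)
  storage.mode(m) <- "double"
  m
}

#' Write / read a parcellation table
#'
#' One row per source: `source`, `roi`, `hemisphere`, `lobe`, `pair`
#' (empty for unpaired regions). The reader reconstructs the per-source ROI
#' index vector and the ROI info table.
#'
#' @param model A `toy_head_model` (or list with `parcellation`, `roi_info`).
#' @param path CSV file path.
#' @return `write_parcellation`: `path` invisibly. `read_parcellation`: a
#'   list with `parcellation` and `roi_info`, usable wherever a model's
#'   parcellation is expected.
#' @export
write_parcellation <- function(model, path) {
  info <- model$roi_info
  df <- data.frame(source = seq_along(model$parcellation),
                   roi = info$roi[model$parcellation],
                   hemisphere = info$hemisphere[model$parcellation],
                   lobe = info$lobe[model$parcellation],
                   pair = info$pair[model$parcellation],
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source", "roi", "hemisphere", "lobe", "pair")
  if (!all(need %in% names(df)))
    stop("parcellation table must have columns: ",
         paste(need, collapse = ", "))
  df <- df[order(df$source), ]
  first <- !duplicated(df$roi)
  info <- data.frame(roi = df$roi[first], hemisphere = df$hemisphere[first],
                     lobe = df$lobe[first],
                     pair = as.integer(df$pair[first]),
                     stringsAsFactors = FALSE)
  list(parcellation = match(df$roi, info$roi), roi_info = info)
}

#' Write abnormality and lateralization tables
#'
#' `write_abnormality` emits the per-cell |z| table (`subject`, `roi`,
#' `band`, `abs_z`) and, alongside it, the per-ROI indicator table
#' (`subject`, `roi`, `max_z`, `argmax_band`) with suffix `_max` before the
#' extension. `write_lateralization` writes the region-pair statistics.
#'
#' @param results An `abnormality_result` or list of them.
#' @param lat A `lateralization_result` data frame.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_abnormality <- function(results, path) {
  if (inherits(results, "abnormality_result")) results <- list(results)
  cell_rows <- list(); max_rows <- list()
  for (i in seq_along(results)) {
    r <- results[[i]]
    id <- if (is.null(r$subject_id)) sprintf("pat%03d", i) else r$subject_id
    cell_rows[[i]] <- data.frame(
      subject = id,
      roi = rep(rownames(r$z_abs), times = ncol(r$z_abs)),
      band = rep(colnames(r$z_abs), each = nrow(r$z_abs)),
      abs_z = as.vector(r$z_abs), stringsAsFactors = FALSE)
    max_rows[[i]] <- data.frame(
      subject = id, roi = rownames(r$z_abs), max_z = r$max_z,
      argmax_band = r$argmax_band, stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, cell_rows), path, row.names = FALSE)
  max_path <- sub("(\\.[^.]+)$", "_max\\1", path)
  utils::write.csv(do.call(rbind, max_rows), max_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abnormality
#' @export
write_lateralization <- function(lat, path) {
  utils::write.csv(as.data.frame(lat), path, row.names = FALSE)
  invisible(path)
}
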