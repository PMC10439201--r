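#' Build a normative map from a cohort of band-power tables
#'
#' Cellwise mean and sample standard deviation (n - 1 denominator) of
#' relative band power across healthy-control subjects. The per-cell SD must
#' be strictly positive for the map to be usable for z-scoring.
#'
#' @param tables List of `region_band_power` matrices (one per subject),
#'   all sharing ROI and band names.
#' @param bands A [band_definition()] recorded as provenance.
#' @param parcellation_id Free-text parcellation identifier.
#' @return Object of class `normative_map`: `mu` and `sigma` (ROI x band
#'   matrices), `n_subjects`, `bands`, `parcellation_id`.
#' @export
build_normative_map <- function(tables, bands = band_definition(),
                                parcellation_id = "toy") {
  if (length(tables) < 2)
    stop("a normative map needs at least 2 subjects (got ", length(tables),
         ")")
  ref <- tables[[1]]
  for (tab in tables[-1]) {
    if (!identical(dim(tab), dim(ref)) ||
        !identical(dimnames(tab), dimnames(ref)))
      stop("all subjects must share the same ROI set and bands")
  }
  arr <- array(unlist(tables), dim = c(nrow(ref), ncol(ref), length(tables)))
  mu <- apply(arr, c(1, 2), mean)
  sigma <- apply(arr, c(1, 2), stats::sd)
  dimnames(mu) <- dimnames(sigma) <- dimnames(ref)
  if (any(sigma <= 0))
    stop("degenerate cohort: zero standard deviation in ",
         sum(sigma <= 0), " cell(s); z-scores would be undefined")
  structure(list(mu = mu, sigma = sigma, n_subjects = length(tables),
                 bands = bands, parcellation_id = parcellation_id),
            class = "normative_map")
}

#' @export
print.normative_map <- function(x, ...) {
  cat(sprintf("normative_map: %d ROIs x %d bands, n = %d (%s)\n",
              nrow(x$mu), ncol(x$mu), x$n_subjects, x$parcellation_id))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their mean rank).
#' Thin contract-checking wrapper over the standard estimator.
#'
#' @param x,y Numeric vectors of equal length >= 3, all values finite.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Epoch-robustness of the normative map
#'
#' Builds one normative map per non-overlapping epoch of the given duration
#' and, for every epoch pair, returns the Spearman correlation between the
#' maps' mean cells (pooled over ROI x band) and between their SD cells.
#' High correlations indicate that the map is stable against the choice of
#' analysis epoch.
#'
#' @param region_ts_list List of `region_ts`, one per control subject.
#' @param epoch_duration_s Epoch length in seconds (default 30).
#' @param n_epochs Number of consecutive epochs to compare; defaults to as
#'   many as the shortest recording holds (at least 2 required).
#' @param ... Passed to [region_band_power()] (Welch settings, bands).
#' @return Data frame with one row per epoch pair: `epoch_a`, `epoch_b`,
#'   `rho_mu`, `rho_sigma`. The per-epoch maps are attached as attribute
#'   `maps`.
#' @export
epoch_robustness <- function(region_ts_list, epoch_duration_s = 30,
                             n_epochs = NULL, ...) {
  min_len <- min(vapply(region_ts_list,
                        function(r) ncol(r$data) / r$fs, numeric(1)))
  max_epochs <- floor(min_len / epoch_duration_s)
  if (is.null(n_epochs)) n_epochs <- max_epochs
  if (n_epochs > max_epochs)
    stop("recordings hold only ", max_epochs, " epochs of ",
         epoch_duration_s, " s")
  if (n_epochs < 2)
    stop("need at least 2 non-overlapping epochs for a robustness analysis")
  maps <- lapply(seq_len(n_epochs) - 1, function(e) {
    tabs <- lapply(region_ts_list, region_band_power,
                   start_s = e * epoch_duration_s,
                   duration_s = epoch_duration_s, ...)
    build_normative_map(tabs)
  })
  pairs <- utils::combn(n_epochs, 2)
  out <- data.frame(
    epoch_a = pairs[1, ], epoch_b = pairs[2, ],
    rho_mu = apply(pairs, 2, function(p)
      spearman(as.vector(maps[[p[1]]]$mu), as.vector(maps[[p[2]]]$mu))),
    rho_sigma = apply(pairs, 2, function(p)
      spearman(as.vector(maps[[p[1]]]$sigma), as.vector(maps[[p[2]]]$sigma)))
  )
  attr(out, "maps") <- maps
  out
}

#' Hemispheric symmetry of a normative map
#'
#' Spearman correlation between left and right homologous regions' mean
#' relative powers, pooled across the five bands. Regions without a
#' homologue are excluded (asymmetric parcellations leave some regions
#' unpaired).
#'
#' @param map A `normative_map`.
#' @param roi_info Parcellation table with `roi`, `hemisphere`, `pair`
#'   columns (or a `toy_head_model`).
#' @param per_band Also return per-band correlations (default FALSE).
#' @return The pooled Spearman rho, with attributes `n_pairs` and `points`
#'   (the (left, right) value pairs); if `per_band`, a list with `rho`,
#'   `rho_per_band`, `n_pairs`.
#' @export
hemispheric_symmetry <- function(map, roi_info, per_band = FALSE) {
  hp <- homologue_pairs(roi_info)
  if (inherits(roi_info, "toy_head_model")) roi_info <- roi_info$roi_info
  li <- match(hp$left, rownames(map$mu))
  ri <- match(hp$right, rownames(map$mu))
  if (any(is.na(li)) || any(is.na(ri)))
    stop("homologue ROI(s) missing from the map: ",
         paste(c(hp$left[is.na(li)], hp$right[is.na(ri)]), collapse = ", "))
  left <- as.vector(map$mu[li, , drop = FALSE])
  right <- as.vector(map$mu[ri, , drop = FALSE])
  rho <- spearman(left, right)
  if (per_band) {
    rho_band <- vapply(seq_len(ncol(map$mu)), function(b)
      spearman(map$mu[li, b], map$mu[ri, b]), numeric(1))
    names(rho_band) <- colnames(map$mu)
    return(list(rho = rho, rho_per_band = rho_band, n_pairs = nrow(hp)))
  }
  attr(rho, "n_pairs") <- nrow(hp)
  attr(rho, "points") <- data.frame(left = left, right = right)
  rho
}

#' Cross-modality comparison of two normative maps
#'
#' Per-band Spearman correlation of mean relative power over the regions
#' common to both maps (matched by label), plus a pooled correlation over
#' all common ROI x band cells. Used to compare a scalp-EEG map against
#' maps from other modalities (MEG, intracranial EEG).
#'
#' @param map_a,map_b `normative_map` objects sharing band names.
#' @return Object of class `map_comparison`: `rho_per_band` (named vector),
#'   `rho_overall`, `n_common_rois`, `unmatched` (labels present in only one
#'   map, reported rather than silently dropped).
#' @export
crossmodal_correlation <- function(map_a, map_b) {
  if (!identical(colnames(map_a$mu), colnames(map_b$mu)))
    stop("maps use different band sets")
  common <- intersect(rownames(map_a$mu), rownames(map_b$mu))
  unmatched <- union(setdiff(rownames(map_a$mu), common),
                     setdiff(rownames(map_b$mu), common))
  if (length(common) < 3)
    stop("need at least 3 common ROIs (got ", length(common), ")")
  a <- map_a$mu[common, , drop = FALSE]
  b <- map_b$mu[common, , drop = FALSE]
  rho_band <- vapply(seq_len(ncol(a)), function(j) spearman(a[, j], b[, j]),
                     numeric(1))
  names(rho_band) <- colnames(a)
  structure(list(rho_per_band = rho_band,
                 rho_overall = spearman(as.vector(a), as.vector(b)),
                 n_common_rois = length(common), unmatched = unmatched),
            class = "map_comparison")
}

#' @export
print.map_comparison <- function(x, ...) {
  cat("map_comparison over", x$n_common_rois, "common ROIs\n")
  print(round(x$rho_per_band, 3))
  cat("pooled rho:", round(x$rho_overall, 3), "\n")
  if (length(x$unmatched))
    cat("unmatched ROIs:", paste(x$unmatched, collapse = ", "), "\n")
  invisible(x)
}
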