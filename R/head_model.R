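#' Construct a toy head model for simulation and testing
#'
#' Builds a geometrically plausible but deliberately simple forward model:
#' sensors on a ring of unit radius, orientation-constrained dipolar sources
#' inside it, and a parcellation that splits regions evenly between the left
#' (x < 0) and right (x > 0) hemispheres. Homologous region pairs are exact
#' mirror images of each other (mirrored source positions and orientations),
#' so the model carries genuine left/right structure for symmetry and
#' lateralization analyses. A configurable number of regions can be left
#' unpaired (placed at the midline), mirroring atlases whose parcellation is
#' not perfectly symmetric.
#'
#' The lead field is computed from a dipole-like gain, the component of the
#' source orientation along the source-to-sensor direction divided by the
#' squared distance, and each column is then normalised to unit Euclidean
#' norm so that sources contribute on a common scale.
#'
#' @param n_sensors Number of sensors (>= 2), equally spaced on the unit ring.
#' @param n_rois Number of regions. Paired regions require
#'   `n_rois - n_unpaired` to be even.
#' @param sources_per_roi Number of constrained sources per region (>= 1).
#' @param seed Integer seed; the model is deterministic given the seed.
#' @param n_unpaired Number of regions without a homologue (default 0).
#' @param n_temporal_pairs Number of homologue pairs tagged as temporal lobe;
#'   defaults to half of the pairs (rounded up).
#'
#' @return An object of class `toy_head_model` with elements:
#'   `leadfield` (n_sensors x n_sources, unit-norm columns),
#'   `source_positions` (n_sources x 3), `parcellation` (integer ROI index per
#'   source), `roi_info` (data frame: `roi`, `hemisphere` ("L"/"R"/"M"),
#'   `lobe` ("temporal"/"other"), `pair` (homologue pair id, NA if unpaired)),
#'   and `sensor_positions`.
#' @export
#' @examples
#' m <- make_toy_head_model(30, 20, 3, seed = 1)
#' dim(m$leadfield)      # 30 x 60
#' table(m$roi_info$hemisphere)
make_toy_head_model <- function(n_sensors, n_rois, sources_per_roi, seed,
                                n_unpaired = 0, n_temporal_pairs = NULL) {
  if (length(n_sensors) != 1 || n_sensors < 2)
    stop("n_sensors must be a single count >= 2")
  if (length(n_rois) != 1 || n_rois < 1)
    stop("n_rois must be a single positive count")
  if (length(sources_per_roi) != 1 || sources_per_roi < 1)
    stop("sources_per_roi must be a single positive count")
  if (n_unpaired < 0 || n_unpaired > n_rois)
    stop("n_unpaired must lie in [0, n_rois]")
  n_paired <- n_rois - n_unpaired
  if (n_paired %% 2 != 0)
    stop("n_rois - n_unpaired must be even to form homologue pairs")
  n_pairs <- n_paired / 2
  if (is.null(n_temporal_pairs)) n_temporal_pairs <- ceiling(n_pairs / 2)
  if (n_temporal_pairs > n_pairs)
    stop("n_temporal_pairs exceeds the number of homologue pairs")

  set.seed(as.integer(seed))

  # Sensors equally spaced on the unit ring (z = 0 plane).
  ang <- seq(0, 2 * pi, length.out = n_sensors + 1)[seq_len(n_sensors)]
  sensor_pos <- cbind(cos(ang), sin(ang), rep(0, n_sensors))

  n_sources <- n_rois * sources_per_roi
  source_pos <- matrix(0, n_sources, 3)
  orient <- matrix(0, n_sources, 3)
  parcellation <- integer(n_sources)

  roi <- data.frame(
    roi = paste0("roi", sprintf("%02d", seq_len(n_rois))),
    hemisphere = rep("M", n_rois),
    lobe = rep("other", n_rois),
    pair = rep(NA_integer_, n_rois),
    stringsAsFactors = FALSE
  )

  # Left-hemisphere parents: centroids spread deterministically over the
  # left half-disc (angles over the left arc, alternating radii, kept clear
  # of the midline so a parcel's field is distinguishable from its
  # mirror's) with sources jittered around the centroid. The right
  # homologue mirrors the source positions but draws its own orientations:
  # homologous cortex is symmetric in location, not in sulcal folding.
  arc <- seq(115, 245, length.out = max(n_pairs, 2))[seq_len(n_pairs)]
  radii <- ifelse(seq_len(n_pairs) %% 2 == 0, 0.5, 0.72)
  idx <- 1L
  for (p in seq_len(n_pairs)) {
    theta <- arc[p] * pi / 180
    centroid <- c(radii[p] * cos(theta), radii[p] * sin(theta),
                  stats::runif(1, -0.1, 0.1))
    pos_l <- sweep(matrix(stats::rnorm(sources_per_roi * 3, sd = 0.05),
                          sources_per_roi, 3), 2, centroid, "+")
    ori_l <- matrix(stats::rnorm(sources_per_roi * 3), sources_per_roi, 3)
    ori_l <- ori_l / sqrt(rowSums(ori_l^2))
    pos_r <- pos_l; pos_r[, 1] <- -pos_r[, 1]
    ori_r <- matrix(stats::rnorm(sources_per_roi * 3), sources_per_roi, 3)
    ori_r <- ori_r / sqrt(rowSums(ori_r^2))

    li <- idx; ri <- idx + 1L
    rows_l <- ((li - 1L) * sources_per_roi + 1L):(li * sources_per_roi)
    rows_r <- ((ri - 1L) * sources_per_roi + 1L):(ri * sources_per_roi)
    source_pos[rows_l, ] <- pos_l; orient[rows_l, ] <- ori_l
    source_pos[rows_r, ] <- pos_r; orient[rows_r, ] <- ori_r
    parcellation[rows_l] <- li; parcellation[rows_r] <- ri
    roi$hemisphere[c(li, ri)] <- c("L", "R")
    roi$pair[c(li, ri)] <- p
    if (p <= n_temporal_pairs) roi$lobe[c(li, ri)] <- "temporal"
    roi$roi[li] <- sprintf("L_%s%02d", roi$lobe[li], p)
    roi$roi[ri] <- sprintf("R_%s%02d", roi$lobe[ri], p)
    idx <- idx + 2L
  }

  # Unpaired regions sit near the midline and carry no pair id.
  for (u in seq_len(n_unpaired)) {
    k <- n_paired + u
    centroid <- c(stats::runif(1, -0.05, 0.05),
                  stats::runif(1, -0.7, 0.7),
                  stats::runif(1, -0.3, 0.3))
    rows <- ((k - 1L) * sources_per_roi + 1L):(k * sources_per_roi)
    source_pos[rows, ] <- sweep(matrix(stats::rnorm(sources_per_roi * 3,
                                                    sd = 0.05),
                                       sources_per_roi, 3), 2, centroid, "+")
    o <- matrix(stats::rnorm(sources_per_roi * 3), sources_per_roi, 3)
    orient[rows, ] <- o / sqrt(rowSums(o^2))
    parcellation[rows] <- k
    roi$roi[k] <- sprintf("M_other%02d", u)
  }

  # Dipole-like gain: projection of the orientation on the source-to-sensor
  # direction, attenuated by squared distance; columns unit-normalised.
  G <- matrix(0, n_sensors, n_sources)
  for (j in seq_len(n_sources)) {
    d <- sweep(sensor_pos, 2, source_pos[j, ], "-")
    r <- sqrt(rowSums(d^2))
    G[, j] <- (d %*% orient[j, ]) / (r^3 + 1e-9)
  }
  G <- sweep(G, 2, sqrt(colSums(G^2)), "/")
  rownames(G) <- paste0("EEG", sprintf("%03d", seq_len(n_sensors)))

  structure(list(
    leadfield = G,
    sensor_positions = sensor_pos,
    source_positions = source_pos,
    source_orientations = orient,
    parcellation = parcellation,
    roi_info = roi
  ), class = "toy_head_model")
}

#' @export
print.toy_head_model <- function(x, ...) {
  cat(sprintf(
    "toy_head_model: %d sensors, %d sources, %d ROIs (%d homologue pairs, %d unpaired)\n",
    nrow(x$leadfield), ncol(x$leadfield), nrow(x$roi_info),
    sum(!is.na(x$roi_info$pair)) / 2, sum(is.na(x$roi_info$pair))))
  invisible(x)
}

#' Validate the structural invariants of a head model
#'
#' Checks that every source belongs to exactly one region and every region
#' owns at least one source, that the lead field is finite with positive rank,
#' and that homologue pairing is symmetric (each pair id names exactly one
#' left and one right region).
#'
#' @param model A `toy_head_model` (or compatible list).
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
validate_head_model <- function(model) {
  G <- model$leadfield
  if (!all(is.finite(G))) stop("lead field contains non-finite entries")
  if (qr(G)$rank < 1) stop("lead field has rank 0")
  n_rois <- nrow(model$roi_info)
  if (length(model$parcellation) != ncol(G))
    stop("parcellation length does not match the number of sources")
  if (!all(model$parcellation %in% seq_len(n_rois)))
    stop("parcellation refers to unknown ROIs")
  counts <- tabulate(model$parcellation, n_rois)
  if (any(counts == 0)) stop("every ROI must own at least one source")
  pairs <- model$roi_info$pair
  for (p in unique(pairs[!is.na(pairs)])) {
    members <- which(pairs == p)
    if (length(members) != 2 ||
        !setequal(model$roi_info$hemisphere[members], c("L", "R")))
      stop("homologue pair ", p, " is not a left/right pair")
  }
  invisible(TRUE)
}

#' Homologue pairs of a head model or parcellation table
#'
#' @param roi_info A data frame with columns `roi`, `hemisphere`, `pair`
#'   (or a `toy_head_model`, whose `roi_info` is used).
#' @return Data frame with one row per pair: `pair`, `left`, `right`
#'   (ROI labels) and `left_idx`, `right_idx` (row indices into `roi_info`).
#' @export
homologue_pairs <- function(roi_info) {
  if (inherits(roi_info, "toy_head_model")) roi_info <- roi_info$roi_info
  ids <- sort(unique(roi_info$pair[!is.na(roi_info$pair)]))
  if (length(ids) == 0) stop("parcellation has no homologue pairs")
  out <- lapply(ids, function(p) {
    li <- which(roi_info$pair == p & roi_info$hemisphere == "L")
    ri <- which(roi_info$pair == p & roi_info$hemisphere == "R")
    data.frame(pair = p, left = roi_info$roi[li], right = roi_info$roi[ri],
               left_idx = li, right_idx = ri, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
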