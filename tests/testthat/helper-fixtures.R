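# Shared fixture builders. Everything is generated in code at test time.

tiny_model <- function(seed = 1, n_sensors = 30, n_rois = 20,
                       sources_per_roi = 3, ...) {
  make_toy_head_model(n_sensors, n_rois, sources_per_roi, seed = seed, ...)
}

# a ROI x band target table with uniform rows
uniform_targets <- function(n_rois, roi_labels = NULL) {
  tab <- matrix(0.2, n_rois, 5)
  colnames(tab) <- c("delta", "theta", "alpha", "beta", "gamma")
  rownames(tab) <- if (is.null(roi_labels))
    paste0("roi", seq_len(n_rois)) else roi_labels
  tab
}

# region_ts wrapper around a bare matrix
as_region_ts <- function(data, fs, labels = NULL) {
  if (is.null(labels)) labels <- paste0("roi", seq_len(nrow(data)))
  rownames(data) <- labels
  structure(list(data = data, fs = fs, roi_labels = labels,
                 flip_signs = rep(1, nrow(data))),
            class = "region_ts")
}

# normative map with given mu/sigma matrices
as_map <- function(mu, sigma, n = 17) {
  structure(list(mu = mu, sigma = sigma, n_subjects = n,
                 bands = band_definition(), parcellation_id = "test"),
            class = "normative_map")
}

# minimal abnormality_result carrying only what lateralize() needs
fake_result <- function(max_z, id = "pat") {
  structure(list(
    z_abs = matrix(max_z, ncol = 1, dimnames = list(names(max_z), "max")),
    z_signed = matrix(max_z, ncol = 1,
                      dimnames = list(names(max_z), "max")),
    max_z = max_z, argmax_band = rep("max", length(max_z)),
    subject_id = id), class = "abnormality_result")
}

# roi_info table for n paired regions (labels L_/R_), first k pairs temporal
fake_roi_info <- function(n_pairs, n_temporal = n_pairs) {
  data.frame(
    roi = as.vector(rbind(paste0("L_p", seq_len(n_pairs)),
                          paste0("R_p", seq_len(n_pairs)))),
    hemisphere = rep(c("L", "R"), n_pairs),
    lobe = rep(ifelse(seq_len(n_pairs) <= n_temporal, "temporal", "other"),
               each = 2),
    pair = rep(seq_len(n_pairs), each = 2),
    stringsAsFactors = FALSE)
}
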