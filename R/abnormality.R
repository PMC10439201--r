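#' Z-score abnormality of a patient against a normative map
#'
#' For every region i and band j the absolute z-score
#' `|z[i,j]| = |x[i,j] - mu[i,j]| / sigma[i,j]` is computed, where x is the
#' patient's relative band power and mu, sigma come from the healthy-control
#' normative map. Because there is usually no band-specific prior
#' hypothesis, the per-region abnormality indicator is the maximum |z|
#' across bands; the band attaining it is recorded, and the signed z table
#' is kept for diagnostics.
#'
#' @param patient A `region_band_power` matrix for one subject.
#' @param map A `normative_map`; ROI and band names must match the patient
#'   table.
#' @param subject_id Optional identifier (defaults to the patient table's
#'   `subject_id` attribute).
#' @return Object of class `abnormality_result`: `z_abs` (ROI x band),
#'   `z_signed`, `max_z` (per ROI), `argmax_band` (per ROI), `subject_id`.
#' @export
zscore_abnormality <- function(patient, map, subject_id = NULL) {
  stopifnot(inherits(map, "normative_map"))
  if (!identical(dimnames(patient), dimnames(map$mu)))
    stop("patient ROIs/bands do not match the normative map")
  if (any(map$sigma <= 0)) stop("normative map has non-positive sigma cells")
  z <- (unclass(patient) - map$mu) / map$sigma
  z_abs <- abs(z)
  arg <- apply(z_abs, 1, which.max)
  if (is.null(subject_id)) subject_id <- attr(patient, "subject_id")
  structure(list(
    z_abs = z_abs, z_signed = z,
    max_z = apply(z_abs, 1, max),
    argmax_band = colnames(z_abs)[arg],
    subject_id = subject_id
  ), class = "abnormality_result")
}

#' @export
print.abnormality_result <- function(x, ...) {
  cat(sprintf("abnormality_result (%s): %d ROIs, top |z| = %.2f at %s (%s)\n",
              if (is.null(x$subject_id)) "unnamed" else x$subject_id,
              nrow(x$z_abs), max(x$max_z),
              rownames(x$z_abs)[which.max(x$max_z)],
              x$argmax_band[which.max(x$max_z)]))
  invisible(x)
}

#' Restrict an abnormality result to temporal-lobe regions
#'
#' @param result An `abnormality_result`.
#' @param roi_info Parcellation table with `roi` and `lobe` columns (or a
#'   `toy_head_model`).
#' @return An `abnormality_result` containing only temporal-labelled ROIs.
#' @export
temporal_subset <- function(result, roi_info) {
  if (inherits(roi_info, "toy_head_model")) roi_info <- roi_info$roi_info
  if (is.null(roi_info$lobe)) stop("parcellation carries no lobe labels")
  keep_rois <- roi_info$roi[roi_info$lobe == "temporal"]
  if (length(keep_rois) == 0) stop("parcellation has no temporal ROIs")
  keep <- rownames(result$z_abs) %in% keep_rois
  if (!any(keep)) stop("no temporal ROIs present in the result")
  structure(list(
    z_abs = result$z_abs[keep, , drop = FALSE],
    z_signed = result$z_signed[keep, , drop = FALSE],
    max_z = result$max_z[keep],
    argmax_band = result$argmax_band[keep],
    subject_id = result$subject_id
  ), class = "abnormality_result")
}

#' Lateralize abnormality across a patient cohort
#'
#' Tests whether abnormality is larger ipsilateral than contralateral to
#' each patient's epileptogenic hemisphere. For every homologous region
#' pair, each patient contributes the max-across-bands |z| of the
#' ipsilateral and of the contralateral member (per that patient's side
#' label); a two-sided paired t-test on the ipsi - contra differences is
#' run across patients, with the paired effect size d_z = mean(diff) /
#' sd(diff) (so d_z = t / sqrt(n)). A positive t means abnormality
#' ipsilateral to the epileptogenic zone.
#'
#' Zero variance of the differences leaves the statistic undefined; an
#' infinite sentinel (signed by the mean difference) is reported with a
#' warning rather than failing silently.
#'
#' @param results List of `abnormality_result`, one per patient.
#' @param sides Character vector ("L"/"R"), the epileptogenic hemisphere per
#'   patient; must be complete.
#' @param roi_info Parcellation table with `roi`, `hemisphere`, `pair`
#'   columns (or a `toy_head_model`). Only pairs whose both members are
#'   present in the results are scored.
#' @param p_adjust Multiple-testing correction across pairs passed to
#'   [stats::p.adjust()]; `"none"` (default) reports raw descriptive p
#'   values, `"BH"` applies Benjamini-Hochberg.
#' @return Data frame (class `lateralization_result`), one row per region
#'   pair: `pair`, `left`, `right`, `mean_ipsi`, `mean_contra`, `t`, `df`,
#'   `p`, `d_z`, `n`.
#' @export
lateralize <- function(results, sides, roi_info, p_adjust = "none") {
  n_pat <- length(results)
  if (n_pat < 2) stop("need at least 2 patients")
  if (length(sides) != n_pat || any(is.na(sides)))
    stop("every patient needs a side label (got ", sum(!is.na(sides)),
         " of ", n_pat, ")")
  if (!all(sides %in% c("L", "R")))
    stop("sides must be 'L' or 'R'")
  hp <- homologue_pairs(roi_info)
  present <- rownames(results[[1]]$z_abs)
  hp <- hp[hp$left %in% present & hp$right %in% present, , drop = FALSE]
  if (nrow(hp) == 0) stop("no homologue pair has both members in the results")

  rows <- lapply(seq_len(nrow(hp)), function(k) {
    ipsi <- numeric(n_pat); contra <- numeric(n_pat)
    for (i in seq_len(n_pat)) {
      zl <- results[[i]]$max_z[hp$left[k]]
      zr <- results[[i]]$max_z[hp$right[k]]
      if (sides[i] == "L") { ipsi[i] <- zl; contra[i] <- zr }
      else { ipsi[i] <- zr; contra[i] <- zl }
    }
    d <- ipsi - contra
    sd_d <- stats::sd(d)
    if (sd_d == 0 && mean(d) == 0) {
      # exact null: ipsi == contra for every patient
      tstat <- 0; dz <- 0; p <- 1
    } else if (sd_d == 0) {
      warning("zero variance of ipsi-contra differences for pair ",
              hp$pair[k], "; t reported as signed infinity")
      tstat <- sign(mean(d)) * Inf
      dz <- tstat
      p <- if (mean(d) == 0) 1 else 0
    } else {
      tstat <- mean(d) / (sd_d / sqrt(n_pat))
      dz <- mean(d) / sd_d
      p <- 2 * stats::pt(-abs(tstat), df = n_pat - 1)
    }
    data.frame(pair = hp$pair[k], left = hp$left[k], right = hp$right[k],
               mean_ipsi = mean(ipsi), mean_contra = mean(contra),
               t = tstat, df = n_pat - 1, p = p, d_z = dz, n = n_pat,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust != "none") out$p_adj <- stats::p.adjust(out$p, p_adjust)
  class(out) <- c("lateralization_result", class(out))
  out
}

#' Pearson chi-square statistic for a 2x2 contingency table
#'
#' Plain Pearson chi-square without continuity correction:
#' `sum((O - E)^2 / E)` with expected counts from the row/column margins.
#' Used for cohort composition comparisons (e.g. sex by group).
#'
#' @param table 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return The chi-square statistic, with attributes `df` and `p`.
#' @export
cohort_contingency_chi2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero margin")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  attr(stat, "df") <- 1
  attr(stat, "p") <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  stat
}

#' Two-sample t-test from summary statistics
#'
#' Compares two group means given only each group's mean, SD and n, as when
#' reproducing statistics from a published cohort table. The default pools
#' the variances (df = n1 + n2 - 2); `welch = TRUE` uses the Welch
#' unequal-variance form with Satterthwaite df.
#'
#' @param mean1,sd1,n1 First group's summary statistics (sd1 > 0, n1 >= 2).
#' @param mean2,sd2,n2 Second group's summary statistics.
#' @param welch Use the Welch variant (default FALSE: pooled variance).
#' @return List: `t`, `df`, `p` (two-sided).
#' @export
cohort_summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 welch = FALSE) {
  if (any(!is.finite(c(mean1, sd1, n1, mean2, sd2, n2))))
    stop("all summary statistics must be finite")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (welch) {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- se^4 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
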