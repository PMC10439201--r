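make_random_map <- function(n_rois = 6, seed = 1) {
  set.seed(seed)
  info <- fake_roi_info(n_rois / 2)
  mu <- matrix(runif(n_rois * 5, 0.05, 0.35), n_rois, 5,
               dimnames = list(info$roi, c("delta", "theta", "alpha",
                                           "beta", "gamma")))
  sigma <- matrix(runif(n_rois * 5, 0.01, 0.05), n_rois, 5,
                  dimnames = dimnames(mu))
  list(map = as_map(mu, sigma), info = info)
}

as_bp <- function(m) { class(m) <- c("region_band_power", class(m)); m }

test_that("z-scoring follows the normative-deviation arithmetic exactly", {
  mm <- make_random_map()
  map <- mm$map
  # null patient: x = mu everywhere
  r0 <- zscore_abnormality(as_bp(map$mu), map)
  expect_true(all(r0$z_abs == 0))
  expect_true(all(r0$max_z == 0))
  # one cell at mu + 2 sigma
  x <- map$mu; x[3, "alpha"] <- x[3, "alpha"] + 2 * map$sigma[3, "alpha"]
  r2 <- zscore_abnormality(as_bp(x), map)
  expect_equal(unname(r2$max_z[3]), 2)
  expect_equal(r2$argmax_band[3], "alpha")
  # absolute value is symmetric: mu - 2 sigma scores the same
  x2 <- map$mu; x2[3, "alpha"] <- x2[3, "alpha"] - 2 * map$sigma[3, "alpha"]
  expect_equal(zscore_abnormality(as_bp(x2), map)$max_z, r2$max_z)
  expect_equal(unname(r2$z_signed[3, "alpha"]), 2)
  expect_equal(unname(zscore_abnormality(as_bp(x2), map)$z_signed[3, "alpha"]),
               -2)
})

test_that("shifting any cell by k sigma shifts its z by exactly k", {
  for (seed in 1:5) {
    mm <- make_random_map(seed = seed)
    map <- mm$map
    for (k in -3:3) {
      x <- map$mu
      x[2, "beta"] <- x[2, "beta"] + k * map$sigma[2, "beta"]
      r <- zscore_abnormality(as_bp(x), map)
      expect_equal(unname(r$z_abs[2, "beta"]), abs(k))
    }
  }
})

test_that("z-scoring enforces alignment and positive sigma", {
  mm <- make_random_map()
  map <- mm$map
  x <- map$mu[1:3, ]
  expect_error(zscore_abnormality(as_bp(x), map), "do not match")
  bad <- map; bad$sigma[1, 1] <- 0
  expect_error(zscore_abnormality(as_bp(bad$mu), bad), "sigma")
})

test_that("temporal subsetting keeps exactly the temporal-labelled regions", {
  info <- fake_roi_info(5, n_temporal = 3)
  mu <- matrix(0.2, 10, 5, dimnames = list(info$roi,
                                           c("delta", "theta", "alpha",
                                             "beta", "gamma")))
  map <- as_map(mu + rnorm(50, sd = 0.001), mu * 0 + 0.02)
  r <- zscore_abnormality(as_bp(map$mu), map)
  tr <- temporal_subset(r, info)
  expect_equal(nrow(tr$z_abs), 6)  # 3 temporal pairs
  expect_true(all(grepl("p[123]$", rownames(tr$z_abs))))
  all_temporal <- info; all_temporal$lobe <- "temporal"
  expect_equal(nrow(temporal_subset(r, all_temporal)$z_abs), 10)
  no_lobe <- info[, c("roi", "hemisphere", "pair")]
  expect_error(temporal_subset(r, no_lobe), "lobe")
})

test_that("paired lateralization reproduces hand-computed statistics", {
  info <- fake_roi_info(1)
  # 4 patients, ipsi - contra differences (2, 0, 1, 3) for the single pair
  ipsi <- c(3, 1, 2, 4); contra <- c(1, 1, 1, 1)
  res <- lapply(1:4, function(i)
    fake_result(stats::setNames(c(ipsi[i], contra[i]), info$roi), i))
  lat <- lateralize(res, rep("L", 4), info)
  expect_equal(lat$t, 2.324, tolerance = 1e-3)
  expect_equal(lat$d_z, 1.162, tolerance = 1e-3)
  expect_equal(lat$n, 4)
  expect_equal(lat$d_z, lat$t / sqrt(lat$n))
  expect_equal(lat$mean_ipsi, 2.5)
  expect_equal(lat$mean_contra, 1)
})

test_that("lateralization nulls and side relabelling behave exactly", {
  info <- fake_roi_info(3)
  set.seed(3)
  vals <- matrix(runif(4 * 6, 0, 3), 6, 4,
                 dimnames = list(info$roi, NULL))
  res <- lapply(1:4, function(i) fake_result(vals[, i], i))
  sides <- c("L", "R", "L", "R")
  lat <- lateralize(res, sides, info)
  flipped <- lateralize(res, ifelse(sides == "L", "R", "L"), info)
  expect_equal(flipped$t, -lat$t)
  expect_equal(flipped$d_z, -lat$d_z)
  # ipsi == contra for every patient -> t = 0
  same <- lapply(1:3, function(i)
    fake_result(stats::setNames(rep(i, 6), info$roi), i))
  lat0 <- lateralize(same, rep("L", 3), info)
  expect_true(all(lat0$t == 0) && all(lat0$d_z == 0))
  # degenerate: constant nonzero difference -> signed infinity with warning
  info1 <- fake_roi_info(1)
  const <- lapply(1:3, function(i)
    fake_result(stats::setNames(c(2, 1), info1$roi), i))
  expect_warning(latc <- lateralize(const, rep("L", 3), info1),
                 "zero variance")
  expect_true(is.infinite(latc$t) && latc$t > 0)
  expect_error(lateralize(res, c("L", "R"), info), "side label")
  expect_error(lateralize(res, c("L", "R", "L", "X"), info), "'L' or 'R'")
  expect_error(lateralize(res[1], "L", info), "at least 2")
})

test_that("lateralization t matches the stats::t.test oracle", {
  info <- fake_roi_info(3)
  set.seed(8)
  n <- 10
  vals <- matrix(runif(6 * n, 0, 4), 6, n, dimnames = list(info$roi, NULL))
  res <- lapply(seq_len(n), function(i) fake_result(vals[, i], i))
  sides <- rep(c("L", "R"), 5)
  lat <- lateralize(res, sides, info)
  hp <- homologue_pairs(info)
  for (k in seq_len(nrow(hp))) {
    ipsi <- ifelse(sides == "L", vals[hp$left[k], ], vals[hp$right[k], ])
    contra <- ifelse(sides == "L", vals[hp$right[k], ], vals[hp$left[k], ])
    tt <- stats::t.test(ipsi, contra, paired = TRUE)
    expect_equal(lat$t[k], unname(tt$statistic))
    expect_equal(lat$p[k], tt$p.value)
  }
})

test_that("Pearson chi-square handles the canonical cases", {
  expect_equal(cohort_contingency_chi2(rbind(c(10, 10), c(10, 10))), 0,
               ignore_attr = TRUE)
  expect_equal(cohort_contingency_chi2(rbind(c(20, 0), c(0, 20))), 40,
               ignore_attr = TRUE)
  # agrees with the uncorrected library test
  tab <- rbind(c(7, 12), c(15, 4))
  expect_equal(as.numeric(cohort_contingency_chi2(tab)),
               unname(stats::chisq.test(tab, correct = FALSE)$statistic))
  expect_error(cohort_contingency_chi2(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(cohort_contingency_chi2(rbind(c(1.5, 1), c(1, 2))), "integer")
  expect_error(cohort_contingency_chi2(matrix(1, 3, 3)), "2x2")
})

test_that("summary-statistic t-test matches raw-data oracles", {
  expect_equal(cohort_summary_ttest(5, 1, 10, 5, 2, 12)$t, 0)
  expect_equal(cohort_summary_ttest(5, 1, 10, 5, 2, 12)$p, 1)
  expect_equal(cohort_summary_ttest(0, 1, 10, 1, 1, 10)$t, -2.236,
               tolerance = 1e-3)
  set.seed(12)
  x <- rnorm(14, 1, 2); y <- rnorm(19, 0.4, 1.3)
  pooled <- cohort_summary_ttest(mean(x), sd(x), 14, mean(y), sd(y), 19)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$t, unname(tt$statistic))
  expect_equal(pooled$p, tt$p.value)
  welch <- cohort_summary_ttest(mean(x), sd(x), 14, mean(y), sd(y), 19,
                                welch = TRUE)
  tw <- stats::t.test(x, y)
  expect_equal(welch$t, unname(tw$statistic))
  expect_equal(welch$df, unname(tw$parameter))
  expect_equal(welch$p, tw$p.value)
  expect_error(cohort_summary_ttest(1, 0, 10, 2, 1, 10), "positive")
  expect_error(cohort_summary_ttest(1, 1, 1, 2, 1, 10), "n >= 2")
})
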