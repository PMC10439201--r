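test_that("normative map cells are cohort mean and sample SD", {
  tabs <- lapply(c(0.2, 0.4, 0.6), function(v) {
    m <- uniform_targets(2)
    m[1, 1] <- v; m[1, ] <- m[1, ] / sum(m[1, ])  # keep rows valid
    m[1, 1] <- v                                   # cell under test
    class(m) <- c("region_band_power", class(m))
    m
  })
  # add distinct values elsewhere so no SD collapses to zero
  for (i in seq_along(tabs)) tabs[[i]][2, ] <- tabs[[i]][2, ] + i * 1e-3
  map <- build_normative_map(tabs)
  expect_equal(map$mu[1, 1], 0.4)
  expect_equal(map$sigma[1, 1], 0.2)   # sample SD, n - 1 denominator
  expect_equal(map$n_subjects, 3)
})

test_that("degenerate cohorts are rejected", {
  tab <- uniform_targets(2)
  class(tab) <- c("region_band_power", class(tab))
  expect_error(build_normative_map(list(tab)), "at least 2")
  expect_error(build_normative_map(list(tab, tab)), "zero standard deviation")
  other <- uniform_targets(3)
  class(other) <- c("region_band_power", class(other))
  expect_error(build_normative_map(list(tab, other)), "same ROI set")
})

test_that("the map is invariant to subject order and recovers the generator", {
  m <- tiny_model(n_rois = 8, sources_per_roi = 1, n_sensors = 4)
  spec <- signal_spec(default_power_profile(m), jitter_sd = 0.10)
  tabs <- sample_band_power(spec, 17, seed = 3)
  map <- build_normative_map(tabs)
  map_perm <- build_normative_map(rev(tabs))
  expect_equal(map$mu, map_perm$mu)
  expect_equal(map$sigma, map_perm$sigma)
  expect_true(all(abs(map$mu - spec$target_relative_power) < 0.03))
})

test_that("spearman matches a rank-then-Pearson oracle and its contracts", {
  expect_equal(spearman(c(1, 2, 3), c(10, 20, 30)), 1)
  expect_equal(spearman(c(1, 2, 3), c(30, 20, 10)), -1)
  set.seed(4)
  for (i in 1:20) {
    x <- sample(1:20, 50, replace = TRUE)  # plenty of ties
    y <- x + rnorm(50, sd = 5)
    oracle <- stats::cor(rank(x, ties.method = "average"),
                         rank(y, ties.method = "average"))
    expect_equal(spearman(x, y), oracle, tolerance = 1e-12)
  }
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:4, 1:5), "equal length")
  expect_error(spearman(c(1, NA, 3), 1:3), "finite")
  # invariance under strictly monotone transforms
  x <- runif(30); y <- runif(30)
  expect_equal(spearman(exp(x), y), spearman(x, y))
})

test_that("epoch robustness is high for stationary cohorts, ~0 for shuffled", {
  m <- tiny_model(n_rois = 10, sources_per_roi = 1, n_sensors = 4)
  spec <- signal_spec(default_power_profile(m), duration_s = 60)
  rts_list <- lapply(1:6, function(i) {
    src <- simulate_source_signals(m, spec, seed = 100 + i)
    as_region_ts(src, 250, m$roi_info$roi)
  })
  rob <- epoch_robustness(rts_list, epoch_duration_s = 30)
  expect_equal(nrow(rob), 1)
  expect_gte(rob$rho_mu, 0.9)
  # shuffled null: regions with unrelated random profiles in each epoch
  # (random row-stochastic targets, so no common band structure survives)
  set.seed(9)
  rand_targets <- function() {
    t <- matrix(stats::runif(10 * 5, 0.02, 1), 10, 5,
                dimnames = dimnames(uniform_targets(10, m$roi_info$roi)))
    t / rowSums(t)
  }
  null_rts <- lapply(1:6, function(i) {
    a <- simulate_source_signals(m, signal_spec(rand_targets(),
                                                duration_s = 30),
                                 seed = 200 + i)
    b <- simulate_source_signals(m, signal_spec(rand_targets(),
                                                duration_s = 30),
                                 seed = 300 + i)
    as_region_ts(cbind(a, b), 250, m$roi_info$roi)
  })
  rob0 <- epoch_robustness(null_rts, epoch_duration_s = 30)
  expect_lt(abs(rob0$rho_mu), 0.5)
  expect_error(epoch_robustness(rts_list, epoch_duration_s = 60),
               "at least 2")
})

test_that("hemispheric symmetry is exact for mirrored maps, null for noise", {
  info <- fake_roi_info(9)
  mu_l <- matrix(runif(9 * 5, 0.05, 0.4), 9, 5)
  mu <- matrix(0, 18, 5, dimnames = list(info$roi, colnames(uniform_targets(1))))
  mu[info$hemisphere == "L", ] <- mu_l
  mu[info$hemisphere == "R", ] <- mu_l          # perfect mirror
  map <- as_map(mu, mu * 0 + 0.02)
  rho <- hemispheric_symmetry(map, info)
  expect_equal(as.numeric(rho), 1)
  expect_equal(attr(rho, "n_pairs"), 9)
  expect_equal(nrow(attr(rho, "points")), 45)   # 9 pairs x 5 bands
  # independent hemispheres: correlation collapses
  set.seed(11)
  rhos <- replicate(20, {
    mu2 <- mu
    mu2[info$hemisphere == "R", ] <- matrix(runif(45, 0.05, 0.4), 9, 5)
    as.numeric(hemispheric_symmetry(as_map(mu2, mu2 * 0 + 0.02), info))
  })
  expect_lt(abs(mean(rhos)), 0.3)
})

test_that("unpaired regions are excluded from the symmetry analysis", {
  m <- tiny_model(n_rois = 20, sources_per_roi = 1, n_sensors = 4,
                  n_unpaired = 2)
  spec <- signal_spec(default_power_profile(m))
  map <- build_normative_map(sample_band_power(spec, 5, seed = 1))
  rho <- hemispheric_symmetry(map, m$roi_info)
  expect_equal(attr(rho, "n_pairs"), 9)
  expect_equal(nrow(attr(rho, "points")), 45)
})

test_that("cross-modality comparison is rank-based per band", {
  info <- fake_roi_info(5)
  mu <- matrix(runif(50, 0.05, 0.4), 10, 5,
               dimnames = list(info$roi, colnames(uniform_targets(1))))
  map <- as_map(mu, mu * 0 + 0.02)
  cmp <- crossmodal_correlation(map, map)
  expect_equal(unname(cmp$rho_per_band), rep(1, 5))
  expect_equal(cmp$rho_overall, 1)
  expect_equal(cmp$n_common_rois, 10)
  # monotone transform leaves every rho at 1
  map_t <- as_map(mu^2, map$sigma)
  expect_equal(unname(crossmodal_correlation(map, map_t)$rho_per_band),
               rep(1, 5))
  # reversing the gamma ranking flips only gamma to -1
  mu_rev <- mu
  mu_rev[, "gamma"] <- max(mu[, "gamma"]) + min(mu[, "gamma"]) - mu[, "gamma"]
  cmp_rev <- crossmodal_correlation(map, as_map(mu_rev, map$sigma))
  expect_equal(unname(cmp_rev$rho_per_band["gamma"]), -1)
  expect_equal(unname(cmp_rev$rho_per_band[c("delta", "theta", "alpha",
                                             "beta")]), rep(1, 4))
  # label mismatches are reported, not dropped silently
  mu_part <- mu[1:6, ]
  cmp_p <- crossmodal_correlation(map, as_map(mu_part, mu_part * 0 + 0.02))
  expect_equal(cmp_p$n_common_rois, 6)
  expect_setequal(cmp_p$unmatched, info$roi[7:10])
  expect_error(crossmodal_correlation(map, as_map(mu[1:2, ],
                                                  mu[1:2, ] * 0 + 0.02)),
               "at least 3 common")
})
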