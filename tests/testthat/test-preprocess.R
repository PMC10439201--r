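test_that("preprocessing reproduces the standard sample-count arithmetic", {
  # 120 s at 5000 Hz, defaults: drop 30 s, resample to 250 Hz -> 22,500 samples
  rec <- sensor_recording(matrix(rnorm(2 * 5000 * 120), 2), fs = 5000)
  out <- preprocess(rec)
  expect_equal(out$fs, 250)
  expect_equal(ncol(out$data), 22500)
  expect_equal(out$channel_labels, rec$channel_labels)
})

test_that("the bandpass rejects 60 Hz and preserves 10 Hz", {
  fs <- 1000; t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  rec60 <- sensor_recording(matrix(sin(2 * pi * 60 * t), 1), fs)
  out60 <- preprocess(rec60, target_fs = 250, discard_initial_s = 5)
  # compare total power: >= 40 dB attenuation
  mid <- seq(1000, ncol(out60$data) - 1000)  # avoid filter edges
  p_out <- mean(out60$data[1, mid]^2)
  expect_lt(10 * log10(p_out / 0.5), -40)

  rec10 <- sensor_recording(matrix(sin(2 * pi * 10 * t), 1), fs)
  out10 <- preprocess(rec10, target_fs = 250, discard_initial_s = 5)
  amp <- sqrt(2 * mean(out10$data[1, mid]^2))
  expect_lt(abs(amp - 1), 0.05)
})

test_that("preprocessing validates its contract", {
  rec <- sensor_recording(matrix(rnorm(500), 1), fs = 250)  # 2 s
  expect_error(preprocess(rec), "shorter")
  expect_error(preprocess(rec, target_fs = 500, discard_initial_s = 0),
               "exceed")
  expect_error(preprocess(rec, target_fs = 250, band = c(1, 200),
                          discard_initial_s = 0), "band")
})

test_that("identity forward model yields an identity-like sLORETA kernel", {
  G <- diag(8)
  inv <- build_sloreta_inverse(G, snr = Inf)
  expect_equal(inv$lambda, 0)
  # kernel equals identity up to per-row positive scaling
  K <- inv$kernel
  expect_true(all(diag(K) > 0))
  expect_lt(max(abs(K - diag(diag(K)))), 1e-10)
})

test_that("the regularization follows the stated SNR rule", {
  m <- tiny_model(n_rois = 4, sources_per_roi = 2, n_sensors = 10)
  i1 <- build_sloreta_inverse(m, snr = 2)
  i2 <- build_sloreta_inverse(m, snr = 4)
  expect_equal(i1$lambda / i2$lambda, 4)
  expect_equal(i1$lambda,
               sum(diag(tcrossprod(m$leadfield))) / (10 * 4))
  expect_error(build_sloreta_inverse(m, snr = 0), "snr")
  expect_error(build_sloreta_inverse(m, noise_cov = matrix(1:100, 10)),
               "symmetric")
})

test_that("inverse application is linear and shape-checked", {
  m <- tiny_model(n_rois = 4, sources_per_roi = 2, n_sensors = 10)
  inv <- build_sloreta_inverse(m)
  zero <- sensor_recording(matrix(0, 10, 50), fs = 250)
  expect_true(all(apply_inverse(zero, inv) == 0))
  x <- sensor_recording(matrix(rnorm(500), 10), fs = 250)
  x3 <- sensor_recording(3 * x$data, fs = 250)
  expect_equal(apply_inverse(x3, inv), 3 * apply_inverse(x, inv))
  expect_error(apply_inverse(matrix(0, 9, 50), inv), "does not match")
})

test_that("sLORETA has zero localization error on a noiseless toy model", {
  m <- tiny_model(seed = 2, n_rois = 20, sources_per_roi = 2,
                  n_sensors = 30)
  inv <- build_sloreta_inverse(m, snr = Inf)
  hits <- vapply(seq_len(ncol(m$leadfield)), function(j) {
    est <- inv$kernel %*% m$leadfield[, j]
    which.max(abs(est)) == j
  }, logical(1))
  expect_true(all(hits))
})

test_that("noiseless round trip recovers region time courses", {
  m <- tiny_model(seed = 4, n_rois = 10, sources_per_roi = 2,
                  n_sensors = 40)
  spec <- signal_spec(default_power_profile(m), duration_s = 20)
  src <- simulate_source_signals(m, spec, seed = 8)
  rec <- project_to_sensors(m, src, noise_sd = 0, fs = 250)
  inv <- build_sloreta_inverse(m, snr = 100)
  rts <- collapse_rois(apply_inverse(rec, inv), m)
  for (k in seq_len(10)) {
    truth <- colMeans(src[m$parcellation == k, , drop = FALSE])
    expect_gte(abs(stats::cor(truth, rts$data[k, ])), 0.9)
  }
})

test_that("sign-flip collapse rescues the cancelling-pair case", {
  s <- sin(seq_len(1000) / 7) + rnorm(1000, sd = 0.1)
  src <- rbind(s, -s)
  model <- list(parcellation = c(1L, 1L),
                roi_info = data.frame(roi = "r1", hemisphere = "L",
                                      lobe = "other", pair = NA))
  out <- collapse_rois(src, model, fs = 250)
  expect_equal(abs(stats::cor(out$data[1, ], s)), 1)
  # naive averaging would annihilate the signal entirely
  expect_lt(stats::sd(colMeans(src)), 1e-12)
})

test_that("a single-source region collapses to itself up to sign", {
  s <- rnorm(500)
  model <- list(parcellation = 1L,
                roi_info = data.frame(roi = "r1", hemisphere = "L",
                                      lobe = "other", pair = NA))
  out <- collapse_rois(matrix(s, 1), model, fs = 100)
  expect_true(isTRUE(all.equal(out$data[1, ], s)) ||
                isTRUE(all.equal(out$data[1, ], -s)))
})

test_that("collapse is invariant to arbitrary source sign flips", {
  set.seed(42)
  m <- tiny_model(n_rois = 4, sources_per_roi = 5, n_sensors = 8)
  spec <- signal_spec(default_power_profile(m), duration_s = 8)
  src <- simulate_source_signals(m, spec, seed = 21)
  src <- src + matrix(rnorm(length(src), sd = 0.2), nrow(src))
  base <- collapse_rois(src, m, fs = 250)
  for (rep in 1:10) {
    flips <- sample(c(-1, 1), nrow(src), replace = TRUE)
    flipped <- collapse_rois(src * flips, m, fs = 250)
    for (k in 1:4) {
      agree <- max(abs(flipped$data[k, ] - base$data[k, ]))
      oppose <- max(abs(flipped$data[k, ] + base$data[k, ]))
      expect_lt(min(agree, oppose), 1e-8)
    }
  }
  expect_error(collapse_rois(src[1:10, ], m, fs = 250), "parcellation")
})
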