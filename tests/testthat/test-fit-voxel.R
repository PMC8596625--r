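te16 <- ute_echo_times()

test_that("noiseless mono decay is recovered to optimizer tolerance", {
  s <- mono_signal(te16, 100, 10)
  f <- fit_mono_voxel(s, te16, 1e-3)
  expect_true(f$converged)
  expect_equal(f$s0, 100, tolerance = 1e-3)
  expect_equal(f$t2star, 10, tolerance = 1e-3)
})

test_that("mono ML log-likelihood dominates a dense grid search on noisy voxels", {
  set.seed(14)
  for (k in 1:5) {
    m <- add_rician_noise(mono_signal(te16, 100, 14.2), 5)
    f <- fit_mono_voxel(m, te16, 5)
    expect_gte(f$loglik, mono_grid_best(m, te16, 5))
  }
})

test_that("degenerate voxels are flagged, not raised", {
  f0 <- fit_mono_voxel(rep(0, 16), te16, 5)
  expect_false(f0$converged)
  expect_identical(f0$flag, "low_snr")
  flow <- fit_mono_voxel(rep(1, 16), te16, 5)
  expect_identical(flow$flag, "low_snr")
  b0 <- fit_bi_voxel(rep(0, 16), te16, 5)
  expect_identical(b0$flag, "low_snr")
})

test_that("noiseless bi-exponential parameters are recovered within 1%", {
  s <- bi_signal(te16, 100, 0.7, 1.0, 15)
  f <- fit_bi_voxel(s, te16, 1e-3)
  expect_true(f$converged)
  expect_equal(f$s0, 100, tolerance = 0.01)
  expect_equal(f$f_short, 0.7, tolerance = 0.01)
  expect_equal(f$t2_short, 1.0, tolerance = 0.01)
  expect_equal(f$t2_long, 15, tolerance = 0.01)
})

test_that("mono-exponential data drive the bi fit onto the nested boundary", {
  s <- mono_signal(te16, 100, 15)
  fm <- fit_mono_voxel(s, te16, 0.5)
  fb <- fit_bi_voxel(s, te16, 0.5)
  expect_lt(abs(fb$loglik - fm$loglik), 1e-6)
  expect_lt(fb$f_short, 0.01)
})

test_that("bi ML log-likelihood dominates a coarse 4-D grid oracle", {
  set.seed(15)
  for (k in 1:3) {
    m <- add_rician_noise(bi_signal(te16, 100, 0.45, 1.1, 14), 5)
    f <- fit_bi_voxel(m, te16, 5)
    expect_gte(f$loglik, bi_grid_best(m, te16, 5))
  }
})

test_that("nesting holds across random voxels: bi log-likelihood >= mono", {
  set.seed(16)
  for (k in 1:20) {
    truth_f <- runif(1)
    m <- add_rician_noise(bi_signal(te16, runif(1, 80, 120), truth_f,
                                    runif(1, 0.6, 1.4), runif(1, 10, 18)), 5)
    fm <- fit_mono_voxel(m, te16, 5)
    fb <- fit_bi_voxel(m, te16, 5)
    expect_gte(fb$loglik, fm$loglik - 1e-6)
  }
})

test_that("Rician ML converges to Gaussian least squares at high SNR", {
  set.seed(17)
  for (k in 1:10) {
    m <- add_rician_noise(mono_signal(te16, 100, 12), 1)  # first-echo SNR 100
    fr <- fit_mono_voxel(m, te16, 1, "rician")
    fg <- fit_mono_voxel(m, te16, 1, "gaussian")
    expect_equal(fr$t2star, fg$t2star, tolerance = 1e-3)
    expect_equal(fr$s0, fg$s0, tolerance = 1e-3)
  }
})

test_that("voxel fits are deterministic and validate their inputs", {
  m <- add_rician_noise(bi_signal(te16, 100, 0.3, 1, 14), 5, seed = 9)
  expect_identical(fit_bi_voxel(m, te16, 5), fit_bi_voxel(m, te16, 5))
  expect_error(fit_mono_voxel(m[1:10], te16, 5), "count")
  expect_error(fit_bi_voxel(m[1:5], te16[1:5], 5), "6 echoes")
  expect_error(fit_mono_voxel(m, te16, 0), "sigma")
})
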