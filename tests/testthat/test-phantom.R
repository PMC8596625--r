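test_that("zero-noise phantom magnitudes equal the noiseless bi-exponential signal", {
  sp <- tiny_phantom_spec(noise_sigma = 0)
  ph <- generate_phantom(sp)
  tr <- ph$truth
  vol <- ph$volumes[[1]]$data
  idx <- which(tr$tendon_mask)
  te <- sp$echo_times
  for (e in seq_along(te)) {
    expected <- bi_signal(te[e], tr$s0_map[idx], tr$fshort_map[idx],
                          tr$t2short_map[idx], tr$t2long_map[idx])
    expect_equal(vol[, , , e][idx], expected)
  }
  # background is exactly zero without noise
  expect_true(all(vol[, , , 1][!tr$tendon_mask] == 0))
})

test_that("zone map proportions follow the constructed concentric geometry", {
  sp <- phantom_spec()
  ph <- generate_phantom(sp)
  zone <- ph$truth$zone_map
  # zones partition the tendon mask and are constant across slices
  expect_identical(zone > 0, ph$truth$tendon_mask)
  for (z in 2:dim(zone)[3]) expect_identical(zone[, , z], zone[, , 1])
  counts <- table(zone[zone > 0])
  expect_identical(as.integer(counts), c(400L, 1200L, 1920L))
  # zone target fractions sit mid-band
  for (k in 1:3) {
    f <- ph$truth$fshort_map[zone == k]
    expect_true(all(abs(f - sp$zone_fractions[k]) <= sp$fraction_jitter + 1e-12))
  }
})

test_that("background magnitudes are Rayleigh with the configured sigma", {
  sp <- phantom_spec(noise_sigma = 5, n_visits = 1L, visit_effects = 0)
  ph <- generate_phantom(sp)
  bg <- !ph$truth$tendon_mask
  m <- ph$volumes[[1]]$data
  vals <- matrix(m, prod(dim(m)[1:3]))[bg, ]   # pooled across echoes
  expect_gt(length(vals), 1e4)
  expect_equal(mean(vals^2) / 2, 25, tolerance = 0.02)
})

test_that("phantom generation is deterministic and truth maps are coherent", {
  sp <- tiny_phantom_spec(noise_sigma = 4)
  a <- generate_phantom(sp); b <- generate_phantom(sp)
  expect_identical(a$volumes[[1]]$data, b$volumes[[1]]$data)
  expect_identical(a$truth, b$truth)
  tr <- a$truth
  msk <- tr$tendon_mask
  expect_true(all(tr$fshort_map[msk] >= 0 & tr$fshort_map[msk] <= 1))
  expect_true(all(tr$t2short_map[msk] < tr$t2long_map[msk]))
})

test_that("visit effects shift only the long component in the degenerative zone", {
  sp <- phantom_spec(grid_shape = c(16L, 16L, 2L), noise_sigma = 0,
                     n_visits = 2L, visit_effects = c(0, -1.3))
  ph <- generate_phantom(sp)
  zone <- ph$truth$zone_map
  t2l_v1 <- ph$truth$t2long_by_visit[[1]]
  t2l_v2 <- ph$truth$t2long_by_visit[[2]]
  expect_equal(t2l_v2[zone == 1], t2l_v1[zone == 1] - 1.3)
  expect_equal(t2l_v2[zone %in% 2:3], t2l_v1[zone %in% 2:3])
})

test_that("invalid phantom specs fail validation naming the field", {
  expect_error(phantom_spec(grid_shape = c(0, 4, 4)), "grid_shape")
  expect_error(phantom_spec(echo_times = c(2, 1, 3)), "echo_times")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  expect_error(phantom_spec(t2s_short_range = c(13, 14)), "t2s_short_range")
  expect_error(phantom_spec(n_visits = 2, visit_effects = c(0, 0, 0)),
               "visit_effects")
})
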