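test_that("short fractions are averaged over the visits where the fit converged", {
  d <- c(2, 2, 1)
  mk <- array(TRUE, d)
  m1 <- array(0.2, d); m2 <- array(0.4, d); m3 <- array(0.6, d)
  expect_equal(average_short_fraction(list(m1, m2, m3), mk),
               array(0.4, d))
  expect_equal(average_short_fraction(list(m1), mk), m1)
  # a non-converged visit is skipped voxel-wise
  m2[1, 1, 1] <- NA
  avg <- average_short_fraction(list(m1, m2), mk)
  expect_equal(avg[1, 1, 1], 0.2)
  expect_equal(avg[2, 2, 1], 0.3)
  # never-converged voxels stay NA
  m1[1, 2, 1] <- NA; m2[1, 2, 1] <- NA
  expect_true(is.na(average_short_fraction(list(m1, m2), mk)[1, 2, 1]))
  expect_error(average_short_fraction(list(m1, array(0.1, c(3, 2, 1))), mk),
               "mismatch")
})

test_that("fraction bands classify with the lower-inclusive convention", {
  fr <- array(c(0.10, 0.45, 0.30, 0.60, 0.999, 0, NA, 0.299), c(8, 1, 1))
  lab <- classify_compartments(fr)
  codes <- compartment_codes()
  expect_identical(as.integer(lab$labels),
                   c(1L, 2L, 2L, 3L, 3L, 1L, 0L, 1L))
  expect_identical(unname(codes["degenerative"]), 1L)
  # partition: every in-mask voxel gets exactly one label
  set.seed(2)
  fr2 <- array(runif(200), c(200, 1, 1))
  lab2 <- classify_compartments(fr2)$labels
  expect_true(all(lab2 %in% 1:3))
  expect_error(classify_compartments(fr, thresholds = c(0.6, 0.3)), "thresholds")
  expect_error(classify_compartments(array(1.4, c(1, 1, 1))), "\\[0, 1\\]")
})

test_that("compartment summaries report the mean and SD of converged voxels", {
  lab <- array(1L, c(2, 1, 1))
  t2 <- array(14.2, c(2, 1, 1))
  rows <- suppressWarnings(compartment_mean_t2(t2, lab, "phantom", 0))
  expect_equal(rows$mean_t2star_ms, 14.2)
  expect_equal(rows$sd_ms, 0)
  expect_equal(rows$n_voxels, 2L)
  t2b <- array(c(10, 20), c(2, 1, 1))
  rows2 <- suppressWarnings(compartment_mean_t2(t2b, lab))
  expect_equal(rows2$mean_t2star_ms, 15)
  expect_equal(rows2$sd_ms, 7.071068, tolerance = 1e-6)
  # empty compartments are omitted with warnings naming them
  w <- capture_warnings(out <- compartment_mean_t2(t2b, lab))
  expect_match(w, "interface", all = FALSE)
  expect_match(w, "aligned_collagen", all = FALSE)
  expect_false("interface" %in% out$compartment)
})

test_that("labels derived from averaged fractions stay constant across visit summaries", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(16L, 16L, 2L),
                                      noise_sigma = 0, n_visits = 2L,
                                      visit_effects = c(0, -1.3)))
  lab <- classify_compartments(
    average_short_fraction(list(ph$truth$fshort_map, ph$truth$fshort_map),
                           ph$truth$tendon_mask))
  # ground-truth fractions sit mid-band, so labels equal the zone map
  expect_identical(lab$labels, ph$truth$zone_map)
  s1 <- suppressWarnings(compartment_mean_t2(ph$truth$t2long_by_visit[[1]], lab,
                                             "p", 0))
  s2 <- suppressWarnings(compartment_mean_t2(ph$truth$t2long_by_visit[[2]], lab,
                                             "p", 24))
  n1 <- s1$n_voxels[s1$compartment == "degenerative"]
  n2 <- s2$n_voxels[s2$compartment == "degenerative"]
  expect_identical(n1, n2)   # same voxel group at both visits
  d <- s2$mean_t2star_ms[s2$compartment == "degenerative"] -
    s1$mean_t2star_ms[s1$compartment == "degenerative"]
  expect_equal(d, -1.3)
})
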