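# Shared fixtures: everything is generated in code at test time.

# A small, fast phantom for unit tests (full 32x32x10 runs in acceptance).
tiny_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(12L, 12L, 2L), n_visits = 1L, visit_effects = 0,
               ...)
}

# Voxels farther than 1 voxel (in-plane 8-neighbourhood) from a zone
# boundary; background counts as a boundary.
zone_interior <- function(zone) {
  interior <- array(FALSE, dim(zone))
  nx <- dim(zone)[1]; ny <- dim(zone)[2]
  for (z in seq_len(dim(zone)[3]))
    for (i in 2:(nx - 1)) for (j in 2:(ny - 1)) {
      nb <- zone[(i - 1):(i + 1), (j - 1):(j + 1), z]
      if (zone[i, j, z] > 0 && all(nb == zone[i, j, z]))
        interior[i, j, z] <- TRUE
    }
  interior
}

# Hand-built four-subject complete cohort with known values, for LOCF and
# schema-level tests.
tiny_cohort <- function() {
  data.frame(
    subject_id = rep(sprintf("S%02d", 1:4), each = 3),
    arm = rep(c("PTLE", "EET"), each = 3, length.out = 12),
    visit_week = rep(c(0, 12, 24), 4),
    t2_degenerative = c(14, 13.5, 13, 15, 14.2, 13.8, 13, 12.5, 12.2, 16, 15.1, 14.7),
    t2_interface = rep(7.5, 12),
    t2_aligned = rep(3.1, 12),
    visap = c(50, 60, 70, 55, 65, 80, 40, 55, 60, 60, 75, 85),
    age = rep(c(22, 25, 28, 31), each = 3),
    sex = rep(c(1, 0, 1, 1), each = 3),
    bmi = rep(c(22.1, 23.4, 24.8, 21.9), each = 3),
    csas = rep(c(80, 75, 90, 65), each = 3),
    symptom_duration = rep(c(52, 104, 78, 30), each = 3),
    scan_missing = FALSE,
    stringsAsFactors = FALSE)
}

# Independent quadrature oracle for log I0(z): the integral representation
# I0(z) = (1/pi) * int_0^pi exp(z cos t) dt, evaluated with the maximum
# factored out so it stays finite at large z.
log_bessel_i0_oracle <- function(z) {
  f <- function(t) exp(z * (cos(t) - 1))
  z + log(stats::integrate(f, 0, pi, rel.tol = 1e-12)$value / pi)
}
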