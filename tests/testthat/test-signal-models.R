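test_that("mono-exponential signal matches its closed form", {
  expect_equal(mono_signal(0, 100, 10), 100)
  expect_equal(mono_signal(10, 100, 10), 100 / exp(1))
  # last echo of the 16-echo protocol at the baseline degenerative T2*
  expect_equal(mono_signal(26.32, 100, 14.2), 100 * exp(-26.32 / 14.2))
  expect_equal(mono_signal(26.32, 100, 14.2), 15.66845, tolerance = 1e-6)
  # monotone non-increasing in TE
  te <- ute_echo_times()
  expect_true(all(diff(mono_signal(te, 80, 7.5)) <= 0))
  expect_error(mono_signal(1, 100, 0), "t2star")
  expect_error(mono_signal(1, 100, -3), "t2star")
})

test_that("bi-exponential signal reduces to mono at the fraction boundaries", {
  te <- ute_echo_times()
  expect_equal(bi_signal(te, 100, 0, 1, 15), mono_signal(te, 100, 15))
  expect_equal(bi_signal(te, 100, 1, 1, 15), mono_signal(te, 100, 1))
  # direct evaluation of the two-pool sum at the fourth echo
  expect_equal(bi_signal(2.92, 100, 0.5, 1, 15),
               50 * exp(-2.92) + 50 * exp(-2.92 / 15))
  expect_equal(bi_signal(2.92, 100, 0.5, 1, 15), 43.85213, tolerance = 1e-6)
  expect_error(bi_signal(1, 100, 0.5, 15, 15), "ordering")
  expect_error(bi_signal(1, 100, 1.2, 1, 15), "f_short")
})

test_that("Rician log-likelihood agrees with Rayleigh closed forms and stays finite at high SNR", {
  expect_equal(rician_loglik(1, 0, 1), -0.5)
  expect_equal(rician_loglik(2, 0, 1), log(2) - 2)
  # finite deep into the high-SNR regime (Bessel argument >= 1e6)
  expect_true(is.finite(rician_loglik(1000, 1000, 1)))
  expect_true(is.finite(rician_loglik(1e4, 1e4, 0.1)))
  expect_identical(rician_loglik(0, 5, 1), -Inf)
  expect_error(rician_loglik(1, 1, 0), "sigma")
})

test_that("log I0 evaluation matches the quadrature oracle across regimes", {
  for (z in c(0.5, 10, 300, 1e3, 1e4, 1e6)) {
    expect_equal(uteT2star:::log_bessel_i0(z), log_bessel_i0_oracle(z),
                 tolerance = 1e-8)
  }
  # the density built from it agrees with a from-scratch evaluation
  m <- 100; a <- 100; s <- 1
  direct <- log(m / s^2) - (m^2 + a^2) / (2 * s^2) +
    log_bessel_i0_oracle(m * a / s^2)
  expect_equal(rician_loglik(m, a, s), direct, tolerance = 1e-6)
})

test_that("analytic amplitude gradient of the log-likelihood matches finite differences", {
  set.seed(1)
  for (k in 1:20) {
    m <- runif(1, 0.5, 200); a <- runif(1, 0.1, 200); s <- runif(1, 0.5, 10)
    h <- 1e-6 * max(a, 1)
    fd <- (rician_loglik(m, a + h, s) - rician_loglik(m, a - h, s)) / (2 * h)
    expect_equal(uteT2star:::rician_dloglik_da(m, a, s), fd,
                 tolerance = 1e-4)
  }
})

test_that("echo protocol validates its schedule", {
  p <- echo_protocol()
  expect_length(p$echo_times, 16L)
  expect_true(all(diff(p$echo_times) > 0))
  expect_equal(p$repetition_time, 83.4)
  expect_equal(p$flip_angle, 17)
  expect_error(echo_protocol(c(1, 2, 3)), "at least 4")
  expect_error(echo_protocol(c(3, 2, 1, 4)), "increasing")
  expect_error(echo_protocol(c(-1, 1, 2, 3)), "positive")
})
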