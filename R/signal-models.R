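#' Echo-time schedule of the 16-echo 3D-UTE-Cones protocol
#'
#' The default multi-echo ultrashort-echo-time protocol: 16 echo times in
#' milliseconds, the first well below 1 msec so that rapidly decaying
#' (short-T2*) collagen-bound water still contributes signal.
#'
#' @return Numeric vector of 16 echo times (msec), strictly increasing.
#' @export
ute_echo_times <- function() {
  c(0.032, 0.49, 0.97, 2.92, 4.87, 6.82, 8.77, 10.72,
    12.67, 14.62, 16.57, 18.52, 20.47, 22.42, 24.37, 26.32)
}

#' Echo protocol descriptor
#'
#' Bundles the echo-time table with acquisition metadata.  Mono-exponential
#' fitting needs at least 4 echoes; bi-exponential fitting at least 6.
#'
#' @param echo_times Echo times in msec, strictly increasing, all positive.
#' @param repetition_time Repetition time in msec (metadata only).
#' @param flip_angle Flip angle in degrees (metadata only).
#' @return An object of class `echo_protocol`.
#' @export
echo_protocol <- function(echo_times = ute_echo_times(),
                          repetition_time = 83.4,
                          flip_angle = 17) {
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) < 4L)
    stop("echo_times: at least 4 echoes are required", call. = FALSE)
  if (any(echo_times <= 0))
    stop("echo_times: all echo times must be positive", call. = FALSE)
  if (any(diff(echo_times) <= 0))
    stop("echo_times: echo times must be strictly increasing", call. = FALSE)
  structure(list(echo_times = echo_times,
                 repetition_time = repetition_time,
                 flip_angle = flip_angle),
            class = "echo_protocol")
}

#' @export
print.echo_protocol <- function(x, ...) {
  cat(sprintf("<echo_protocol> %d echoes, TE %.3f-%.2f msec, TR %.1f msec, FA %g deg\n",
              length(x$echo_times), min(x$echo_times), max(x$echo_times),
              x$repetition_time, x$flip_angle))
  invisible(x)
}

#' Mono-exponential T2* decay signal
#'
#' Noiseless magnitude signal `s0 * exp(-te / t2star)` of a single water
#' pool at echo time `te`.
#'
#' @param te Echo time(s), msec, non-negative.
#' @param s0 Signal amplitude at TE = 0 (arbitrary units), non-negative.
#' @param t2star Effective transverse relaxation time, msec, positive.
#' @return Signal amplitude(s), same length as the longest argument.
#' @export
mono_signal <- function(te, s0, t2star) {
  if (any(t2star <= 0)) stop("t2star must be positive", call. = FALSE)
  if (any(s0 < 0)) stop("s0 must be non-negative", call. = FALSE)
  if (any(te < 0)) stop("te must be non-negative", call. = FALSE)
  s0 * exp(-te / t2star)
}

#' Bi-exponential T2* decay signal
#'
#' Two-pool noiseless signal
#' `s0 * (f_short * exp(-te/t2_short) + (1 - f_short) * exp(-te/t2_long))`.
#' `f_short` is the amplitude fraction of the short-T2* (collagen-bound)
#' pool at TE = 0; `100 * f_short` is the percentage of short-T2* components.
#'
#' @param te Echo time(s), msec, non-negative.
#' @param s0 Amplitude at TE = 0, non-negative.
#' @param f_short Short-pool fraction in [0, 1].
#' @param t2_short Short-component T2*, msec.
#' @param t2_long Long-component T2*, msec; must exceed `t2_short`.
#' @return Signal amplitude(s).
#' @export
bi_signal <- function(te, s0, f_short, t2_short, t2_long) {
  if (any(f_short < 0 | f_short > 1))
    stop("f_short must lie in [0, 1]", call. = FALSE)
  if (any(t2_short <= 0)) stop("t2_short must be positive", call. = FALSE)
  if (any(t2_short >= t2_long))
    stop("component ordering violated: t2_short must be < t2_long", call. = FALSE)
  if (any(s0 < 0)) stop("s0 must be non-negative", call. = FALSE)
  if (any(te < 0)) stop("te must be non-negative", call. = FALSE)
  s0 * (f_short * exp(-te / t2_short) + (1 - f_short) * exp(-te / t2_long))
}

#' Rician log-likelihood of a magnitude observation
#'
#' Log-density of the Rician distribution,
#' `log[(m/sigma^2) exp(-(m^2+a^2)/(2 sigma^2)) I0(m a / sigma^2)]`,
#' evaluated with the exponentially scaled Bessel function so it stays
#' finite at high signal-to-noise (arguments `m*a/sigma^2` of 1e6 and
#' beyond).  At `a = 0` this is the Rayleigh log-density.  `m = 0` returns
#' `-Inf` (the density vanishes at the origin).
#'
#' @param m Observed magnitude(s), non-negative.
#' @param a Noiseless signal amplitude(s), non-negative.
#' @param sigma Rician scale (Gaussian noise SD per channel), positive.
#' @return Log-density in nats, vectorized over `m` and `a`.
#' @export
rician_loglik <- function(m, a, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  if (any(m < 0)) stop("m must be non-negative", call. = FALSE)
  if (any(a < 0)) stop("a must be non-negative", call. = FALSE)
  z <- m * a / sigma^2
  log(m) - 2 * log(sigma) - (m^2 + a^2) / (2 * sigma^2) + log_bessel_i0(z)
}

# log I0(z), finite for arbitrarily large z.  R's besselI (even
# exponentially scaled) underflows to 0 beyond z ~ 1e5, so switch to the
# large-argument expansion
#   I0(z) ~ e^z / sqrt(2 pi z) * (1 + 1/(8z) + 9/(128 z^2) + 225/(3072 z^3))
# above z = 700, where its relative error is below 1e-12.
log_bessel_i0 <- function(z) {
  out <- numeric(length(z))
  small <- z <= 700
  if (any(small))
    out[small] <- log(besselI(z[small], 0, expon.scaled = TRUE)) + z[small]
  if (any(!small)) {
    zl <- z[!small]
    out[!small] <- zl - 0.5 * log(2 * pi * zl) +
      log1p(1 / (8 * zl) + 9 / (128 * zl^2) + 225 / (3072 * zl^3))
  }
  out
}

# Ratio I1(z)/I0(z), needed by the analytic gradient of the Rician
# log-likelihood; same large-z switch as log_bessel_i0, using
# I1/I0 ~ 1 - 1/(2z) - 1/(8 z^2) - 1/(8 z^3).
bessel_i1i0 <- function(z) {
  r <- numeric(length(z))
  small <- z <= 700
  if (any(small))
    r[small] <- besselI(z[small], 1, expon.scaled = TRUE) /
      besselI(z[small], 0, expon.scaled = TRUE)
  if (any(!small)) {
    zl <- z[!small]
    r[!small] <- 1 - 1 / (2 * zl) - 1 / (8 * zl^2) - 1 / (8 * zl^3)
  }
  r
}

# d/da of rician_loglik, vectorized: -a/sigma^2 + (m/sigma^2) * I1/I0(ma/s^2)
rician_dloglik_da <- function(m, a, sigma) {
  s2 <- sigma^2
  (-a + m * bessel_i1i0(m * a / s2)) / s2
}
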