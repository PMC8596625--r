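#' Add Rician noise to noiseless signal amplitudes
#'
#' Draws the magnitude of a complex Gaussian perturbation of the clean
#' signal: `m = sqrt((a + g1*sigma)^2 + (g2*sigma)^2)` with independent
#' standard-normal `g1`, `g2`.  This is the noise law of magnitude MRI
#' reconstructed from a single coil; at `a = 0` the output is Rayleigh.
#' `sigma = 0` returns the input unchanged.  Deterministic under `seed`.
#'
#' @param clean Array/vector of non-negative noiseless amplitudes.
#' @param sigma Rician scale (per-channel Gaussian SD), non-negative.
#' @param seed Optional integer; when supplied the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return Array of magnitudes, same shape as `clean`.
#' @export
add_rician_noise <- function(clean, sigma, seed = NULL) {
  if (length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("sigma must be a single non-negative number", call. = FALSE)
  if (any(clean < 0)) stop("clean amplitudes must be non-negative", call. = FALSE)
  if (sigma == 0) return(clean)
  draw <- function() {
    n <- length(clean)
    g1 <- stats::rnorm(n)
    g2 <- stats::rnorm(n)
    m <- sqrt((as.numeric(clean) + g1 * sigma)^2 + (g2 * sigma)^2)
    if (!is.null(dim(clean))) dim(m) <- dim(clean)
    m
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
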