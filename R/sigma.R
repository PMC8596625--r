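#' Estimate the Rician noise scale from image background
#'
#' In signal-free background the magnitude is Rayleigh distributed with
#' second moment `E[m^2] = 2 sigma^2`, so
#' `sigma_hat = sqrt(mean(m^2) / 2)` over background voxels pooled across
#' all echoes.  One global sigma per acquisition is assumed (single-coil
#' noise floor, spatially uniform).
#'
#' @param volume A [multiecho_volume()].
#' @param background_mask Logical/0-1 3D array on the volume grid marking
#'   signal-free voxels; must be non-empty and should be disjoint from any
#'   tissue mask.
#' @return Estimated sigma (positive scalar).
#' @export
estimate_sigma <- function(volume, background_mask) {
  stopifnot(inherits(volume, "multiecho_volume"))
  d <- dim(volume$data)
  if (!identical(dim(background_mask), d[1:3]))
    stop(sprintf("grid mismatch: background mask is %s, volume %s",
                 paste(dim(background_mask), collapse = "x"),
                 paste(d[1:3], collapse = "x")), call. = FALSE)
  bg <- as.logical(background_mask)
  if (!any(bg)) stop("background mask is empty", call. = FALSE)
  m <- matrix(volume$data, nrow = prod(d[1:3]))[bg, , drop = FALSE]
  if (all(m == 0))
    stop("background voxels are all zero; cannot estimate sigma", call. = FALSE)
  sqrt(mean(m^2) / 2)
}
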