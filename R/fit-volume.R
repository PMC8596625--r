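#' Fit mono- and bi-exponential models over a masked volume
#'
#' Estimates the global noise scale from the background region (unless
#' `sigma` is supplied), then runs [fit_mono_voxel()] and [fit_bi_voxel()]
#' at every tendon voxel.  Voxels outside the mask are left `NA`.
#' Convergence counts are reported via `message()`.
#'
#' @param volume A [multiecho_volume()].
#' @param tendon_mask Logical 3D array marking tendon voxels.
#' @param background_mask Logical 3D array of signal-free voxels for noise
#'   estimation; ignored when `sigma` is given.
#' @param sigma Optional known noise scale (e.g. for noiseless phantoms
#'   where no background signal exists); positive.
#' @param bounds,control,n_polish Passed to the voxel fitters.
#' @return A `fit_maps` list: `sigma`, `mono` (maps `s0`, `t2star`,
#'   `loglik`, `converged`), `bi` (maps `s0`, `f_short`, `t2_short`,
#'   `t2_long`, `loglik`, `converged`), `quality_mask` (both fits
#'   converged), `tendon_mask`, and convergence counts.
#' @export
fit_volume <- function(volume, tendon_mask, background_mask = NULL,
                       sigma = NULL, bounds = default_fit_bounds(),
                       control = list(factr = 4.5e6, maxit = 400L),
                       n_polish = 1L) {
  stopifnot(inherits(volume, "multiecho_volume"))
  d <- dim(volume$data)
  if (!identical(dim(tendon_mask), d[1:3]))
    stop(sprintf("grid mismatch: tendon mask is %s, volume %s",
                 paste(dim(tendon_mask), collapse = "x"),
                 paste(d[1:3], collapse = "x")), call. = FALSE)
  mask <- as.logical(tendon_mask)
  if (is.null(sigma)) {
    if (is.null(background_mask))
      stop("either a background mask or an explicit sigma is required",
           call. = FALSE)
    if (any(as.logical(background_mask) & mask))
      stop("background mask overlaps the tendon mask", call. = FALSE)
    sigma <- estimate_sigma(volume, background_mask)
  }
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)

  blank <- function() array(NA_real_, d[1:3])
  mono <- list(s0 = blank(), t2star = blank(), loglik = blank(),
               converged = array(FALSE, d[1:3]))
  bi <- list(s0 = blank(), f_short = blank(), t2_short = blank(),
             t2_long = blank(), loglik = blank(),
             converged = array(FALSE, d[1:3]))

  idx <- which(mask)
  sig_mat <- matrix(volume$data, nrow = prod(d[1:3]))
  te <- volume$echo_times
  screen <- make_bi_screen(te, bounds)
  for (v in idx) {
    s <- sig_mat[v, ]
    mf <- fit_mono_voxel(s, te, sigma, bounds = bounds, control = control)
    mono$s0[v] <- mf$s0; mono$t2star[v] <- mf$t2star
    mono$loglik[v] <- mf$loglik; mono$converged[v] <- mf$converged
    bf <- fit_bi_voxel(s, te, sigma, bounds = bounds, control = control,
                       n_polish = n_polish, screen = screen, mono = mf)
    bi$s0[v] <- bf$s0; bi$f_short[v] <- bf$f_short
    bi$t2_short[v] <- bf$t2_short; bi$t2_long[v] <- bf$t2_long
    bi$loglik[v] <- bf$loglik; bi$converged[v] <- bf$converged
  }
  quality <- mono$converged & bi$converged & mask
  n_mask <- length(idx)
  message(sprintf(
    "fit_volume: sigma_hat = %.4g; %d/%d mono and %d/%d bi fits converged",
    sigma, sum(mono$converged), n_mask, sum(bi$converged), n_mask))
  structure(list(sigma = sigma, mono = mono, bi = bi,
                 quality_mask = quality, tendon_mask = mask,
                 n_mask = n_mask,
                 n_mono_converged = sum(mono$converged),
                 n_bi_converged = sum(bi$converged)),
            class = "fit_maps")
}

#' @export
print.fit_maps <- function(x, ...) {
  cat(sprintf("<fit_maps> %d tendon voxels, sigma_hat = %.4g, mono %d/%d, bi %d/%d converged\n",
              x$n_mask, x$sigma, x$n_mono_converged, x$n_mask,
              x$n_bi_converged, x$n_mask))
  invisible(x)
}
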