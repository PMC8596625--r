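# Tissue-compartment segmentation from the visit-averaged short-T2*
# fraction, and compartment-mean mono-exponential T2* summaries.

#' Compartment label codes
#'
#' Integer codes used in label maps: 0 = excluded/background,
#' 1 = degenerative, 2 = interface, 3 = aligned_collagen.
#'
#' @return Named integer vector.
#' @export
compartment_codes <- function() {
  c(excluded = 0L, degenerative = 1L, interface = 2L, aligned_collagen = 3L)
}

#' Average the short-T2* fraction over visits
#'
#' Voxel-wise arithmetic mean of the bi-exponential short fraction across
#' visits, using only the visits at which the voxel's fit converged
#' (non-`NA`).  Voxels converged at no visit are `NA` (excluded
#' downstream).
#'
#' @param fshort_maps List of 3D fraction maps, one per visit; `NA` marks
#'   non-converged voxels.
#' @param tendon_mask Logical 3D array; voxels outside are `NA` in the
#'   output.
#' @return 3D map of averaged fractions.
#' @export
average_short_fraction <- function(fshort_maps, tendon_mask) {
  if (length(fshort_maps) < 1L) stop("at least one visit map is required", call. = FALSE)
  dims <- dim(fshort_maps[[1]])
  for (m in fshort_maps)
    if (!identical(dim(m), dims))
      stop("grid mismatch between visit maps", call. = FALSE)
  if (!identical(dim(tendon_mask), dims))
    stop("grid mismatch between maps and tendon mask", call. = FALSE)
  stack <- array(unlist(fshort_maps), c(dims, length(fshort_maps)))
  avg <- apply(stack, 1:3, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  })
  avg[!as.logical(tendon_mask)] <- NA_real_
  avg
}

#' Classify tendon voxels into tissue compartments
#'
#' Thresholds the visit-averaged short-T2* fraction into three bands:
#' below the first threshold is degenerative tissue (mostly long T2*),
#' between the thresholds the interface, and at or above the second
#' threshold aligned collagen (mostly short T2*).  Intervals are half-open,
#' lower-inclusive: with the default thresholds, a fraction of exactly 0.30
#' is interface and 0.60 is aligned collagen.  `NA` fractions become
#' `excluded`.  The resulting label map is intended to be computed once
#' from all visits and then applied unchanged to every visit.
#'
#' @param avg_fraction 3D map from [average_short_fraction()], values in
#'   [0, 1] or `NA`.
#' @param thresholds Two ordered fractions in (0, 1); default
#'   `c(0.30, 0.60)`.
#' @return A `compartment_labels` object: integer 3D `labels` array (codes
#'   per [compartment_codes()]) with attributes recording the thresholds.
#' @export
classify_compartments <- function(avg_fraction, thresholds = c(0.30, 0.60)) {
  if (length(thresholds) != 2L || thresholds[1] >= thresholds[2] ||
      any(thresholds <= 0) || any(thresholds >= 1))
    stop(sprintf("thresholds must be two increasing fractions in (0,1), got (%s)",
                 paste(thresholds, collapse = ", ")), call. = FALSE)
  ok <- !is.na(avg_fraction)
  if (any(avg_fraction[ok] < 0 | avg_fraction[ok] > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  labels <- array(0L, dim(avg_fraction))
  labels[ok & avg_fraction < thresholds[1]] <- 1L
  labels[ok & avg_fraction >= thresholds[1] & avg_fraction < thresholds[2]] <- 2L
  labels[ok & avg_fraction >= thresholds[2]] <- 3L
  structure(list(labels = labels, thresholds = thresholds,
                 n_visits_averaged = attr(avg_fraction, "n_visits")),
            class = "compartment_labels")
}

#' @export
print.compartment_labels <- function(x, ...) {
  tab <- table(factor(x$labels[x$labels > 0L], levels = 1:3,
                      labels = names(compartment_codes())[-1]))
  cat(sprintf("<compartment_labels> thresholds %.2f/%.2f; %s\n",
              x$thresholds[1], x$thresholds[2],
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Compartment-mean mono-exponential T2* for one visit
#'
#' Averages the mono-exponential T2* map over the converged voxels of each
#' tissue compartment, using a label map held constant over visits.
#' Compartments with no usable voxels are omitted with a warning.
#'
#' @param t2star_map 3D mono-exponential T2* map (msec) for one visit;
#'   `NA` marks non-converged or unfitted voxels.
#' @param labels A [classify_compartments()] result (or integer label
#'   array using the same codes).
#' @param subject_id,visit_week Identifiers copied into the output rows.
#' @return Data frame with columns `subject_id`, `visit_week`,
#'   `compartment`, `mean_t2star_ms`, `sd_ms`, `n_voxels`.
#' @export
compartment_mean_t2 <- function(t2star_map, labels,
                                subject_id = NA_character_,
                                visit_week = NA_real_) {
  lab <- if (inherits(labels, "compartment_labels")) labels$labels else labels
  if (!identical(dim(t2star_map), dim(lab)))
    stop("grid mismatch between T2* map and label map", call. = FALSE)
  rows <- lapply(1:3, function(code) {
    vals <- t2star_map[lab == code]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) {
      warning(sprintf("compartment '%s' has no usable voxels; row omitted",
                      names(compartment_codes())[code + 1L]), call. = FALSE)
      return(NULL)
    }
    data.frame(subject_id = subject_id, visit_week = visit_week,
               compartment = names(compartment_codes())[code + 1L],
               mean_t2star_ms = mean(vals),
               sd_ms = if (length(vals) > 1L) stats::sd(vals) else 0,
               n_voxels = length(vals))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
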