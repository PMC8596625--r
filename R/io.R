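# NIfTI-1 / YAML / CSV interchange.  Multi-echo volumes travel as 4D
# NIfTI with echo along the 4th dimension; NIfTI has no echo-time field,
# so a YAML sidecar carries the protocol.

#' Write a multi-echo volume as 4D NIfTI plus a YAML protocol sidecar
#'
#' @param volume A [multiecho_volume()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @param protocol_path Optional YAML sidecar path; defaults to
#'   `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_multiecho <- function(volume, path, protocol_path = paste0(path, ".yaml")) {
  stopifnot(inherits(volume, "multiecho_volume"))
  # magnitude volumes are stored at full precision so simulate -> fit chains
  # are exactly reproducible from disk; parameter maps use float32
  RNifti::writeNifti(volume$data, path, datatype = "double")
  write_protocol(echo_protocol(volume$echo_times), protocol_path)
  invisible(path)
}

#' Read a multi-echo volume from 4D NIfTI
#'
#' Validates that the 4th dimension matches the protocol's echo count and
#' clips negative voxels to zero (magnitude data are non-negative), with a
#' warning stating how many were clipped.
#'
#' @param path NIfTI file with echo along dimension 4.
#' @param protocol An [echo_protocol()], a numeric echo-time vector, or a
#'   YAML sidecar path.
#' @return A [multiecho_volume()].
#' @export
read_multiecho <- function(path, protocol) {
  if (is.character(protocol)) protocol <- read_protocol(protocol)
  te <- if (inherits(protocol, "echo_protocol")) protocol$echo_times
        else as.numeric(protocol)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) == 3L) arr <- array(arr, c(dim(arr), 1L))
  if (length(dim(arr)) != 4L)
    stop(sprintf("expected a 4D volume, got %d dimensions", length(dim(arr))),
         call. = FALSE)
  if (dim(arr)[4] != length(te))
    stop(sprintf("echo count mismatch: file has %d volumes, protocol %d echo times",
                 dim(arr)[4], length(te)), call. = FALSE)
  n_neg <- sum(arr < 0)
  if (n_neg > 0) {
    warning(sprintf("clipped %d negative voxel value(s) to zero", n_neg),
            call. = FALSE)
    arr[arr < 0] <- 0
  }
  multiecho_volume(arr, te)
}

#' Write / read an echo protocol as YAML
#'
#' @param protocol An [echo_protocol()].
#' @param path YAML path.
#' @return The path (write) or an [echo_protocol()] (read).
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "echo_protocol"))
  yaml::write_yaml(list(echo_times_msec = protocol$echo_times,
                        repetition_time_msec = protocol$repetition_time,
                        flip_angle_deg = protocol$flip_angle), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  echo_protocol(echo_times = y$echo_times_msec,
                repetition_time = y$repetition_time_msec %||% 83.4,
                flip_angle = y$flip_angle_deg %||% 17)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a parameter map or mask as NIfTI
#'
#' Parameter maps are written as float32, masks/labels as uint8.
#'
#' @param map 3D numeric (or logical/integer) array.
#' @param path Output path.
#' @param type `"float"` for parameter maps, `"uint8"` for masks/labels.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, type = c("float", "uint8")) {
  type <- match.arg(type)
  if (type == "uint8") {
    storage.mode(map) <- "integer"
    RNifti::writeNifti(map, path, datatype = "uint8")
  } else {
    RNifti::writeNifti(map, path, datatype = "float")
  }
  invisible(path)
}

#' Read a 3D map written by [write_map()]
#' @param path NIfTI path.
#' @return 3D array.
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

#' Write a cohort table as CSV
#'
#' @param cohort Cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#' @param path CSV path.
#' @return Data frame with the cohort schema.
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
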