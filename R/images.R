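# Calibrated image containers. Images are numeric matrices in detector counts
# (0-255); rows index y, columns x. Pixel size in um/px is mandatory: all
# downstream areas and lengths are physical.

#' Calibrated single-channel image
#'
#' A 2D fluorescence (or brightfield) plane together with the metadata the
#' pipeline needs: pixel size (um/px), the channel role and the exposure time
#' used to acquire it.
#'
#' @param data Numeric matrix of intensities (detector counts, 0-255).
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param channel Channel role, e.g. "dapi", "cd45", "epithelial",
#'   "mesenchymal", "brightfield", "red", "green", "aqua".
#' @param exposure_ms Exposure time in milliseconds (optional metadata).
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(data, pixel_size_um, channel = "dapi", exposure_ms = NA_real_) {
  if (!is.matrix(data) || !is.numeric(data)) stop("`data` must be a numeric matrix")
  stop_if_not_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  structure(
    list(data = data, pixel_size_um = pixel_size_um,
         channel = as.character(channel), exposure_ms = exposure_ms),
    class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s: %d x %d px @ %.3g um/px (exposure %s ms)\n",
              x$channel, nrow(x$data), ncol(x$data), x$pixel_size_um,
              format(x$exposure_ms)))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$data)

#' z-stack series for one channel
#'
#' An ordered series of optical sections of a single channel. Plane j sits at
#' axial position `z_um[j]` (um, in the specimen frame); consecutive planes
#' are `step_um` apart and the whole comb spans `(n_stacks - 1) * step_um`.
#'
#' @param planes 3D numeric array `[y, x, z]` of intensities, or a list of
#'   matrices (all the same size).
#' @param step_um Axial distance between consecutive planes (um).
#' @param z_um Axial position of each plane (um). Defaults to a comb centred
#'   on zero.
#' @param pixel_size_um Lateral pixel size (um/px).
#' @param channel Channel role.
#' @param exposure_ms Exposure time (ms).
#' @param origin_um Length-2 (x, y) position (um) of the centre of pixel
#'   (row 1, column 1); defaults to half a pixel (corner-origin frame).
#'   Detected spot positions are reported in this frame.
#' @return An object of class `zstack_series`.
#' @export
zstack_series <- function(planes, step_um, z_um = NULL, pixel_size_um,
                          channel = "red", exposure_ms = NA_real_,
                          origin_um = NULL) {
  if (is.list(planes)) {
    stopifnot(length(planes) >= 1L)
    d <- dim(planes[[1]])
    planes <- array(unlist(planes, use.names = FALSE), dim = c(d, length(planes)))
  }
  if (!is.array(planes) || length(dim(planes)) != 3L)
    stop("`planes` must be a [y, x, z] array or list of matrices")
  stop_if_not_scalar_num(step_um, "step_um", positive = TRUE)
  stop_if_not_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  n <- dim(planes)[3]
  if (is.null(z_um)) z_um <- (seq_len(n) - (n + 1) / 2) * step_um
  if (length(z_um) != n) stop("`z_um` must have one entry per plane")
  if (is.null(origin_um)) origin_um <- c(pixel_size_um / 2, pixel_size_um / 2)
  structure(
    list(planes = planes, step_um = step_um, z_um = z_um,
         pixel_size_um = pixel_size_um, channel = as.character(channel),
         exposure_ms = exposure_ms, origin_um = as.numeric(origin_um)),
    class = "zstack_series")
}

#' @export
print.zstack_series <- function(x, ...) {
  n <- dim(x$planes)[3]
  cat(sprintf(
    "<zstack_series> %s: %d planes of %d x %d px, step %.2f um (span %.1f um)\n",
    x$channel, n, dim(x$planes)[1], dim(x$planes)[2], x$step_um,
    (n - 1) * x$step_um))
  invisible(x)
}

#' Number of planes in a z-stack series
#' @param x A `zstack_series`.
#' @return Integer plane count.
#' @export
n_planes <- function(x) {
  stopifnot(inherits(x, "zstack_series"))
  dim(x$planes)[3]
}
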