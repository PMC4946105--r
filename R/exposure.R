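# Detector exposure model. The scanner acquires 8-bit images with the gain
# fixed at its maximum (255) and exposure time as the only intensity control;
# exposure is calibrated per channel within 5-100 ms.

#' Detector exposure model
#'
#' Linear 8-bit detector response:
#' `counts = clip(dark_level + k * photon_rate * exposure_ms + noise, 0, 255)`.
#' Monotone non-decreasing in exposure and saturating exactly at 255. Gain is
#' a fixed scale (maximum 255 by convention); the exposure time is the only
#' per-channel intensity control, which keeps settings comparable across scans.
#'
#' @param gain Detector scale tag (default 255, the maximum).
#' @param dark_level Offset counts present with zero light.
#' @param k Conversion factor from photon-rate units to counts per ms.
#' @param read_noise_sd Gaussian read-noise standard deviation (counts);
#'   0 gives a deterministic response.
#' @param shot_noise Logical; add approximate shot noise (Gaussian with
#'   variance equal to the signal counts).
#' @return An object of class `exposure_model`.
#' @export
exposure_model <- function(gain = 255, dark_level = 8, k = 1,
                           read_noise_sd = 1.5, shot_noise = TRUE) {
  stop_if_not_scalar_num(dark_level, "dark_level")
  stop_if_not_scalar_num(k, "k", positive = TRUE)
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  structure(list(gain = gain, dark_level = dark_level, k = k,
                 read_noise_sd = read_noise_sd, shot_noise = isTRUE(shot_noise)),
            class = "exposure_model")
}

#' Expose a photon-rate image
#'
#' Applies the detector response to a photon-rate image at a given exposure
#' time. The deterministic part is pointwise monotone in `exposure_ms`;
#' values clip at 0 and saturate at 255 and are quantized to whole counts.
#' Because brighter exposure lifts more of a spot's flanks over any fixed
#' threshold, the above-threshold footprint of a signal is non-decreasing in
#' exposure (until saturation flattens its core into a plateau).
#'
#' @param rate Numeric matrix (or array) of photon rates (units: counts per
#'   ms per `k`).
#' @param exposure_ms Exposure time in ms; must lie in `[5, 100]`.
#' @param model An [exposure_model()].
#' @param noise Logical; apply the model's noise terms. Noise uses the
#'   caller's RNG state - seed outside for reproducibility.
#' @return Matrix/array of integer-valued counts in `[0, 255]`.
#' @export
apply_exposure <- function(rate, exposure_ms, model = exposure_model(), noise = TRUE) {
  stopifnot(inherits(model, "exposure_model"))
  stop_if_not_scalar_num(exposure_ms, "exposure_ms")
  if (exposure_ms < 5 || exposure_ms > 100)
    stop("exposure_ms must be within [5, 100] ms")
  signal <- model$k * rate * exposure_ms
  counts <- model$dark_level + signal
  if (isTRUE(noise)) {
    n <- length(counts)
    eps <- rnorm(n, sd = model$read_noise_sd)
    if (model$shot_noise) eps <- eps + rnorm(n, sd = sqrt(pmax(signal, 0)))
    counts <- counts + eps
  }
  out <- clamp(round(counts), 0, 255)
  storage.mode(out) <- "double"
  dim(out) <- dim(rate)
  out
}
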