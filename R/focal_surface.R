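# The membrane is not microscopically flat: the true focus height varies
# smoothly across a spot. The scanner compensates by pre-focusing on a grid
# of focus points and refocusing on DAPI every frame; what remains is a
# smooth surface plus a per-frame refocus residual.

#' Smooth focal surface of a filter spot
#'
#' True focus height `z0(x, y)` (um) modelled as a low-order 2D polynomial in
#' coordinates normalized to the field, scaled to a configurable peak-to-peak
#' amplitude. The per-frame DAPI refocus leaves a residual Gaussian error of
#' `refocus_sd_um`.
#'
#' @param field_um Length-2 field size (x, y) in um over which the surface is
#'   normalized.
#' @param peak_to_peak_um Height range of the surface over the field (um).
#' @param refocus_sd_um Residual per-frame refocus error sd (um).
#' @param coefficients Optional 3 x 3 matrix of polynomial coefficients
#'   `c[i, j]` multiplying `u^(i-1) * v^(j-1)` (u, v in [-1, 1]). Random
#'   smooth coefficients are drawn when omitted.
#' @param seed Seed for random coefficients.
#' @return Object of class `focal_surface`; evaluate with [eval_surface()].
#' @export
focal_surface <- function(field_um = c(1000, 1000), peak_to_peak_um = 10,
                          refocus_sd_um = 0.5, coefficients = NULL, seed = NULL) {
  stopifnot(length(field_um) == 2L)
  if (peak_to_peak_um < 0) stop("peak_to_peak_um must be >= 0")
  if (is.null(coefficients)) {
    coefficients <- with_seed(seed, matrix(rnorm(9), 3, 3))
    coefficients[1, 1] <- 0
  }
  stopifnot(is.matrix(coefficients), all(dim(coefficients) == c(3, 3)))
  surf <- structure(
    list(field_um = as.numeric(field_um), coefficients = coefficients,
         peak_to_peak_um = peak_to_peak_um, refocus_sd_um = refocus_sd_um,
         scale = 1),
    class = "focal_surface")
  # calibrate scale so the realized peak-to-peak over the field matches
  g <- expand.grid(x = seq(0, field_um[1], length.out = 61),
                   y = seq(0, field_um[2], length.out = 61))
  z <- eval_surface(surf, g$x, g$y)
  rng <- diff(range(z))
  surf$scale <- if (rng > 0) peak_to_peak_um / rng else 0
  surf
}

#' Evaluate a focal surface
#'
#' @param surface A [focal_surface()].
#' @param x_um,y_um Coordinates in um (vectors of equal length).
#' @return Focus heights `z0(x, y)` in um.
#' @export
eval_surface <- function(surface, x_um, y_um) {
  stopifnot(inherits(surface, "focal_surface"))
  u <- 2 * x_um / surface$field_um[1] - 1
  v <- 2 * y_um / surface$field_um[2] - 1
  cf <- surface$coefficients
  z <- 0
  for (i in 1:3) for (j in 1:3)
    if (cf[i, j] != 0) z <- z + cf[i, j] * u^(i - 1) * v^(j - 1)
  surface$scale * z
}

# Residual per-frame refocus error (uses caller RNG).
refocus_error <- function(surface, n = 1) {
  rnorm(n, sd = surface$refocus_sd_um)
}
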