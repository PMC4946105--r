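# Filter-spot geometry: the pore lattice and the snick fiducial.

#' Filter-spot geometry
#'
#' Describes the physical membrane: circular pores of `pore_diameter_um` on a
#' hexagonal lattice with centre-to-centre distance `pore_pitch_um`, a spot
#' of `spot_diameter_mm`, and the "snick" - the asymmetric notch cut into the
#' spot rim that serves as the fiducial for relocating cells between
#' staining/scanning rounds. The snick must be orientation-resolving, so its
#' shape is a scalene notch (no mirror or rotational symmetry).
#'
#' @param pore_diameter_um Pore diameter (um); membrane standard is 8.
#' @param pore_pitch_um Pore centre-to-centre spacing (um).
#' @param spot_diameter_mm Spot diameter (mm); one spot filters 1 mL blood.
#' @param snick List describing the notch: `angle_deg` (position on the rim),
#'   `depth_um` (radial depth) and `skew` (asymmetry factor, != 0.5 so the two
#'   notch flanks differ and the outline resolves orientation).
#' @return An object of class `filter_geometry`.
#' @export
filter_geometry <- function(pore_diameter_um = 8, pore_pitch_um = 20,
                            spot_diameter_mm = 6,
                            snick = list(angle_deg = 30, depth_um = 250, skew = 0.3)) {
  stop_if_not_scalar_num(pore_diameter_um, "pore_diameter_um", positive = TRUE)
  stop_if_not_scalar_num(pore_pitch_um, "pore_pitch_um", positive = TRUE)
  stop_if_not_scalar_num(spot_diameter_mm, "spot_diameter_mm", positive = TRUE)
  if (pore_pitch_um <= pore_diameter_um)
    stop("pore_pitch_um must exceed pore_diameter_um (pores must not overlap)")
  if (isTRUE(all.equal(snick$skew, 0.5)))
    stop("snick skew of 0.5 makes the fiducial mirror-symmetric (ambiguous)")
  structure(
    list(pore_diameter_um = pore_diameter_um, pore_pitch_um = pore_pitch_um,
         spot_diameter_mm = spot_diameter_mm, snick = snick),
    class = "filter_geometry")
}

#' @export
print.filter_geometry <- function(x, ...) {
  cat(sprintf(
    "<filter_geometry> %.1f-mm spot, %.0f-um pores (area %.1f um^2) on %.0f-um pitch\n",
    x$spot_diameter_mm, x$pore_diameter_um, pore_area_um2(x$pore_diameter_um),
    x$pore_pitch_um))
  invisible(x)
}

#' Hexagonal pore lattice within a rectangular field
#'
#' Pore centres (um) of the hexagonal lattice covering a `field_um[1]` x
#' `field_um[2]` rectangle (x by y).
#'
#' @param geometry A [filter_geometry()].
#' @param field_um Numeric length-2: field width and height in um.
#' @return Data frame with columns `x_um`, `y_um`.
#' @export
pore_lattice <- function(geometry, field_um) {
  stopifnot(inherits(geometry, "filter_geometry"), length(field_um) == 2L)
  p <- geometry$pore_pitch_um
  dy <- p * sqrt(3) / 2
  rows <- seq(0, field_um[2] + dy, by = dy)
  out <- lapply(seq_along(rows), function(i) {
    xoff <- if (i %% 2 == 0) p / 2 else 0
    xs <- seq(xoff, field_um[1] + p, by = p)
    data.frame(x_um = xs, y_um = rows[i])
  })
  out <- do.call(rbind, out)
  out[out$x_um <= field_um[1] & out$y_um <= field_um[2], , drop = FALSE]
}

#' Snick fiducial outline
#'
#' Polyline (um) tracing the notch cut into the spot rim, in spot-centred
#' coordinates. The notch is a scalene wedge: its two flanks subtend different
#' arcs (controlled by `skew`), so the traced outline has no mirror or
#' rotational symmetry and registration between rounds is unambiguous.
#'
#' @param geometry A [filter_geometry()].
#' @param n_points Number of polyline points.
#' @return An `n_points` x 2 matrix of (x, y) in um.
#' @export
snick_outline <- function(geometry, n_points = 80) {
  stopifnot(inherits(geometry, "filter_geometry"))
  R <- geometry$spot_diameter_mm * 1000 / 2
  s <- geometry$snick
  depth <- s$depth_um
  half_arc <- 2 * depth / R          # angular half-width of the notch (rad)
  a0 <- s$angle_deg * pi / 180
  skew <- s$skew
  # rim approach -> deep vertex (offset toward one flank) -> rim exit
  t <- seq(0, 1, length.out = n_points)
  # piecewise: in [0, skew] descend along flank 1; in (skew, 1] ascend flank 2
  ang <- a0 - half_arc + t * 2 * half_arc
  frac <- ifelse(t <= skew, t / skew, (1 - t) / (1 - skew))
  r <- R - depth * frac
  cbind(x_um = r * cos(ang), y_um = r * sin(ang))
}
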