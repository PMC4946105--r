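# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

#' Area of one filter pore
#'
#' Area in um^2 of a circular pore of the given diameter. The 8-um default
#' pore has an area of ~50 um^2, the unit used by the pore-equivalent area
#' gates (55 um^2 single-cell gate, 150 um^2 = three pore-equivalents for
#' clusters).
#'
#' @param pore_diameter_um Pore diameter in micrometres.
#' @return Area in um^2 (numeric scalar).
#' @examples
#' round(pore_area_um2(8))  # 50
#' @export
pore_area_um2 <- function(pore_diameter_um = 8) {
  stop_if_not_scalar_num(pore_diameter_um, "pore_diameter_um", positive = TRUE)
  pi * (pore_diameter_um / 2)^2
}

#' Equivalent-circle diameter of an area
#'
#' Diameter (um) of the circle having the given area (um^2). Centralizes the
#' area <-> diameter conversion the size gates rely on (e.g. nuclear area
#' 55 um^2 vs nucleus diameter 16 um rules).
#'
#' @param area_um2 Area(s) in um^2.
#' @return Diameter(s) in um.
#' @export
equiv_diameter_um <- function(area_um2) {
  if (any(area_um2 < 0, na.rm = TRUE)) stop("area must be >= 0")
  2 * sqrt(area_um2 / pi)
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L) stop("`seed` must be a single integer")
  withr::with_seed(as.integer(seed), code)
}

# Clamp numeric vector/matrix into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
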