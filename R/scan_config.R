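# FISH scanning configuration. The scanner tolerates at most 30 z-stacks;
# exposures are calibrated within 5-100 ms, up to three exposure times per
# FISH channel (with three channels, up to 27 settings in theory; with red
# and green only, 9 - both cardinalities are valid configurations).

#' FISH scan configuration
#'
#' @param n_stacks Number of z-stacks (optical sections), 1-30; default 30,
#'   the established optimum (and the scanner's maximum).
#' @param step_um Distance between consecutive z-stacks (um); default 0.6,
#'   the established optimum (sweeps use 0.5-0.8).
#' @param exposures_ms Named list, one numeric vector (1-3 exposure times,
#'   each within 5-100 ms) per FISH channel.
#' @param gain Detector gain tag (max 255).
#' @param offset Detector offset (counts).
#' @param n_focus_points Pre-scan focus points across the filter (default 9).
#' @param magnification Magnification tag (FISH capture at x63).
#' @return Object of class `scan_config`.
#' @export
scan_config <- function(n_stacks = 30, step_um = 0.6,
                        exposures_ms = list(red = c(20, 50, 100),
                                            green = c(20, 50, 100)),
                        gain = 255, offset = 0, n_focus_points = 9,
                        magnification = "x63") {
  if (!is.numeric(n_stacks) || n_stacks < 1 || n_stacks != round(n_stacks))
    stop("n_stacks must be a positive integer")
  if (n_stacks > 30)
    stop("n_stacks must be <= 30 (scanner maximum)")
  stop_if_not_scalar_num(step_um, "step_um", positive = TRUE)
  if (!is.list(exposures_ms) || is.null(names(exposures_ms)))
    stop("exposures_ms must be a named list (one vector per channel)")
  if (length(exposures_ms) > 3)
    stop("at most 3 FISH channels are supported")
  for (ch in names(exposures_ms)) {
    e <- exposures_ms[[ch]]
    if (length(e) < 1 || length(e) > 3)
      stop("1-3 exposure times per channel (channel '", ch, "')")
    if (any(e < 5 | e > 100))
      stop("exposure times must lie within [5, 100] ms (channel '", ch, "')")
  }
  structure(list(n_stacks = as.integer(n_stacks), step_um = step_um,
                 exposures_ms = exposures_ms, gain = gain, offset = offset,
                 n_focus_points = n_focus_points, magnification = magnification),
            class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf(
    "<scan_config> %d z-stacks x %.2f um (span %.1f um), %s; %d exposure settings\n",
    x$n_stacks, x$step_um, (x$n_stacks - 1) * x$step_um, x$magnification,
    prod(vapply(x$exposures_ms, length, integer(1)))))
  invisible(x)
}

#' Axial plane positions of a scan
#'
#' Comb of optical-section heights (um) relative to the comb centre; the comb
#' spans `(n_stacks - 1) * step_um`.
#'
#' @param scan A [scan_config()].
#' @param center_um Comb centre height (um), e.g. the per-frame DAPI refocus.
#' @return Numeric vector of plane heights.
#' @export
plane_positions <- function(scan, center_um = 0) {
  stopifnot(inherits(scan, "scan_config"))
  center_um + (seq_len(scan$n_stacks) - (scan$n_stacks + 1) / 2) * scan$step_um
}
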