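# Simulation of per-cell FISH z-stacks. CTC nuclei on filters are thick
# (up to >30 um across, ~8-14 um deep) and sit on an uneven membrane, so
# break-apart spots are spread over an axial range that a too-short z-comb
# misses. Spots are rendered as 3D Gaussians (lateral sd 0.4 um, axial sd
# 0.8 um by default); a plane records a spot only when it sections the
# spot's axial support.

#' Point-spread / rendering parameters for FISH spots
#'
#' @param lateral_sd_um Lateral Gaussian sd of a rendered spot (um).
#' @param axial_sd_um Axial Gaussian sd (um).
#' @param axial_support_um A plane records a spot only when the plane-spot
#'   axial distance is strictly below this half-width (um): the optical
#'   section must cut the spot's core. With the 0.3-um default a 0.6-um step
#'   tiles z completely while coarser steps leave dead zones - the mechanism
#'   behind the step sweep's interior optimum.
#' @return Object of class `fish_psf`.
#' @export
fish_psf <- function(lateral_sd_um = 0.4, axial_sd_um = 0.8,
                     axial_support_um = 0.3) {
  structure(list(lateral_sd_um = lateral_sd_um, axial_sd_um = axial_sd_um,
                 axial_support_um = axial_support_um),
            class = "fish_psf")
}

#' Simulate a cohort of FISH cells with known spot truth
#'
#' Each cell gets a thick nucleus, an axial offset (residual of the per-frame
#' DAPI refocus against the uneven membrane) and break-apart FISH spots drawn
#' from its pattern: `native` (2 fused red/green pairs), `rearranged` (1
#' fused pair + 1 split pair), `gain` (3-6 fused pairs, no split). Spot z
#' positions are uniform within the nucleus thickness.
#'
#' @param n_cells Number of cells.
#' @param patterns Character vector of patterns (recycled), or a named
#'   probability vector over `c("native", "rearranged", "gain")`.
#' @param nucleus_diameter_um Nucleus diameter (um).
#' @param nucleus_thickness_um Nucleus axial thickness (um); spots span this.
#' @param z_offset_sd_um Sd of the per-cell comb-centre error (um).
#' @param spot_rate Peak photon rate of a spot (counts/ms units).
#' @param pair_sep_fused_um,pair_sep_split_um Red-green separation of fused
#'   and split pairs (um).
#' @param seed Integer seed.
#' @return List of `fish_cell` objects: each has `id`, `pattern`,
#'   `nucleus_diameter_um`, `thickness_um`, `z_offset_um` and `spots` (data
#'   frame `x_um`, `y_um`, `z_um`, `channel`, `rate`, `pair`, `pair_type`).
#' @export
simulate_fish_cells <- function(n_cells = 20,
                                patterns = c(native = 0.3, rearranged = 0.5, gain = 0.2),
                                nucleus_diameter_um = 20,
                                nucleus_thickness_um = 14,
                                z_offset_sd_um = 1.5,
                                spot_rate = 4,
                                pair_sep_fused_um = 0.4,
                                pair_sep_split_um = 3,
                                seed = 1) {
  with_seed(seed, {
    if (!is.null(names(patterns)) && is.numeric(patterns)) {
      pat <- sample(names(patterns), n_cells, replace = TRUE, prob = patterns)
    } else {
      pat <- rep_len(as.character(patterns), n_cells)
    }
    lapply(seq_len(n_cells), function(i) {
      R <- nucleus_diameter_um / 2
      tz <- nucleus_thickness_um
      n_pairs <- switch(pat[i], native = 2L, rearranged = 2L,
                        gain = sample(3:6, 1), stop("unknown pattern ", pat[i]))
      split_pair <- if (pat[i] == "rearranged") n_pairs else 0L
      rows <- list()
      for (p in seq_len(n_pairs)) {
        # pair anchor uniform in the nucleus disc and thickness
        rr <- R * 0.8 * sqrt(runif(1)); aa <- runif(1, 0, 2 * pi)
        cx <- rr * cos(aa); cy <- rr * sin(aa)
        cz <- runif(1, -tz / 2, tz / 2)
        sep <- if (p == split_pair) pair_sep_split_um else pair_sep_fused_um
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        half <- sep / 2 * dir
        rows[[length(rows) + 1]] <- data.frame(
          x_um = cx + c(half[1], -half[1]), y_um = cy + c(half[2], -half[2]),
          z_um = clamp(cz + c(half[3], -half[3]), -tz / 2, tz / 2),
          channel = c("red", "green"),
          rate = spot_rate * runif(2, 0.7, 1.3), pair = p,
          pair_type = if (p == split_pair) "split" else "fused",
          stringsAsFactors = FALSE)
      }
      structure(
        list(id = i, pattern = pat[i], nucleus_diameter_um = nucleus_diameter_um,
             thickness_um = tz, z_offset_um = rnorm(1, sd = z_offset_sd_um),
             spots = do.call(rbind, rows)),
        class = "fish_cell")
    })
  })
}

#' Render a z-stack of one FISH cell
#'
#' Optical sections are taken at the comb positions of `scan`, centred on the
#' cell's refocused height: `z0(x, y)` from the focal surface (when given)
#' plus the cell's residual `z_offset_um`. A spot contributes to plane j only
#' when `|z_spot - z_j|` is strictly below the PSF's axial support, with
#' Gaussian axial and lateral intensity fall-off; the comb spans
#' `(n_stacks - 1) * step_um`, so spots outside the comb (plus support) are
#' absent from every plane.
#'
#' @param cell A `fish_cell` (or a bare data frame of spots).
#' @param scan A [scan_config()].
#' @param channel Channel to render (`"red"` or `"green"`).
#' @param exposure_ms Exposure time (ms); defaults to the first configured
#'   exposure of the channel.
#' @param surface Optional [focal_surface()]; adds `z0` at the cell position
#'   to the comb centre and the spot heights cancel it (the DAPI refocus
#'   tracks the surface), leaving only the residual refocus error.
#' @param psf A [fish_psf()].
#' @param model An [exposure_model()].
#' @param pixel_size_um Lateral pixel size (um/px); x63 capture, default 0.2.
#' @param field_um Lateral field width/height (um); defaults to the nucleus
#'   plus margin.
#' @param noise Logical; detector noise (uses caller RNG).
#' @return A [zstack_series()] with `z_um` relative to the comb centre.
#' @export
render_zstack <- function(cell, scan, channel = "red", exposure_ms = NULL,
                          surface = NULL, psf = fish_psf(),
                          model = exposure_model(), pixel_size_um = 0.2,
                          field_um = NULL, noise = TRUE) {
  stopifnot(inherits(scan, "scan_config"))
  spots <- if (inherits(cell, "fish_cell")) cell$spots else cell
  if (is.null(exposure_ms))
    exposure_ms <- scan$exposures_ms[[channel]][1] %||% 50
  if (is.null(field_um)) {
    field_um <- if (inherits(cell, "fish_cell")) cell$nucleus_diameter_um + 6 else 20
  }
  z_center <- if (inherits(cell, "fish_cell")) cell$z_offset_um else 0
  # comb centre error: surface height is tracked by the per-frame DAPI
  # refocus, so only its residual (already in z_offset_um) remains; an
  # explicit surface adds its refocus residual draw.
  if (!is.null(surface)) z_center <- z_center + refocus_error(surface)
  zs <- plane_positions(scan, z_center)
  npx <- as.integer(ceiling(field_um / pixel_size_um))
  ax <- (seq_len(npx) - (npx + 1) / 2) * pixel_size_um
  sel <- spots$channel == channel
  sp <- spots[sel, , drop = FALSE]
  planes <- array(0, dim = c(npx, npx, scan$n_stacks))
  for (j in seq_len(scan$n_stacks)) {
    rate <- matrix(0, npx, npx)
    if (nrow(sp)) {
      dz <- sp$z_um - zs[j]
      hit <- abs(dz) < psf$axial_support_um
      for (k in which(hit)) {
        amp <- sp$rate[k] * exp(-dz[k]^2 / (2 * psf$axial_sd_um^2))
        gx <- exp(-(ax - sp$x_um[k])^2 / (2 * psf$lateral_sd_um^2))
        gy <- exp(-(ax - sp$y_um[k])^2 / (2 * psf$lateral_sd_um^2))
        rate <- rate + amp * outer(gy, gx)
      }
    }
    planes[, , j] <- apply_exposure(rate, exposure_ms, model, noise = noise)
  }
  zstack_series(planes, step_um = scan$step_um, z_um = zs - z_center,
                pixel_size_um = pixel_size_um, channel = channel,
                exposure_ms = exposure_ms, origin_um = c(ax[1], ax[1]))
}
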