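# Cross-round relocation and cytomorphological CTC calling. The snick cut
# into the spot rim is the fiducial that links the fluorescence round to the
# cytomorphology (or FISH) round; an asymmetric outline makes the rigid
# alignment unambiguous.

#' Rigid transform between scanning rounds
#'
#' @param rotation_deg Rotation angle (degrees, counter-clockwise).
#' @param translation_um Length-2 translation (um), applied after rotation.
#' @param mirror Logical; reflect x before rotating (slide flipped).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = 0, translation_um = c(0, 0), mirror = FALSE) {
  stopifnot(length(translation_um) == 2L)
  structure(list(rotation_deg = rotation_deg,
                 translation_um = as.numeric(translation_um),
                 mirror = isTRUE(mirror)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot %.3f deg, shift (%.2f, %.2f) um%s\n",
              x$rotation_deg, x$translation_um[1], x$translation_um[2],
              if (x$mirror) ", mirrored" else ""))
  if (!is.null(attr(x, "residual_um")))
    cat(sprintf("  fiducial residual %.3f um RMS\n", attr(x, "residual_um")))
  invisible(x)
}

#' Apply / invert / compose rigid transforms
#'
#' `apply_transform` maps an n x 2 matrix of points (um); composition with
#' the inverse returns the identity (distances are preserved exactly).
#'
#' @param tf,a,b `rigid_transform` objects.
#' @param pts n x 2 numeric matrix of (x, y) in um.
#' @return Transformed points / the inverse / the composition `a` then `b`.
#' @export
apply_transform <- function(tf, pts) {
  stopifnot(inherits(tf, "rigid_transform"))
  pts <- rbind(pts)  # accept a single point as a vector
  if (tf$mirror) pts[, 1] <- -pts[, 1]
  th <- tf$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(pts %*% t(R), 2, tf$translation_um, `+`)
}

#' @rdname apply_transform
#' @export
invert_transform <- function(tf) {
  if (tf$mirror) {
    # T(x) = R M x + t  =>  T^-1(y) = R(theta) M y - M R(-theta) t
    th <- -tf$rotation_deg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    t_new <- -(R %*% tf$translation_um)
    t_new[1] <- -t_new[1]
    rigid_transform(tf$rotation_deg, as.numeric(t_new), mirror = TRUE)
  } else {
    th <- -tf$rotation_deg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    rigid_transform(-tf$rotation_deg, as.numeric(-(R %*% tf$translation_um)))
  }
}

#' @rdname apply_transform
#' @export
compose_transform <- function(a, b) {
  # x -> b(a(x)); mirrored composition only supported for non-mirrored b
  if (b$mirror) stop("composition with a mirrored outer transform is not supported")
  th <- b$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rigid_transform(a$rotation_deg + b$rotation_deg,
                  as.numeric(R %*% a$translation_um + b$translation_um),
                  mirror = a$mirror)
}

# Resample a polyline to n points equally spaced by arc length.
resample_polyline <- function(pts, n = 200) {
  pts <- as.matrix(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0) stop("degenerate outline (zero length)")
  si <- seq(0, s[length(s)], length.out = n)
  cbind(stats::approx(s, pts[, 1], xout = si)$y,
        stats::approx(s, pts[, 2], xout = si)$y)
}

# Kabsch: least-squares rigid fit mapping A onto B (correspondence assumed).
kabsch <- function(A, B, allow_mirror = FALSE) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- t(Ac) %*% Bc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (!allow_mirror && d < 0) return(NULL)
  S <- diag(c(1, d))
  R <- sv$v %*% S %*% t(sv$u)
  t_vec <- cb - as.numeric(R %*% ca)
  fitted <- sweep(Ac %*% t(R), 2, cb, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  rot <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  list(rotation_deg = rot, translation_um = t_vec, rmsd = rmsd, det = d,
       # collinear point sets leave the rotation underdetermined
       degenerate = sv$d[2] <= 1e-8 * max(sv$d[1], .Machine$double.xmin))
}

#' Register two scanning rounds from their snick outlines
#'
#' Resamples both fiducial outlines by arc length and fits the rigid
#' transform (Kabsch/SVD) mapping round A onto round B, trying both traversal
#' directions (and, optionally, a mirrored slide). The best fit is returned
#' with its RMS fiducial residual; if a second alignment fits almost as well
#' the fiducial is effectively symmetric and registration is refused as
#' ambiguous.
#'
#' @param outline_a,outline_b n x 2 point matrices (um) tracing the snick in
#'   each round. An `NULL`/empty outline means the snick was not detected.
#' @param n_resample Number of arc-length resampling points.
#' @param allow_mirror Also try a reflected fit.
#' @param max_residual_um Refuse fits whose residual exceeds this (um).
#' @param ambiguity_ratio Error if the runner-up residual is within this
#'   factor of the best.
#' @return A [rigid_transform()] with attribute `residual_um`.
#' @export
register_rounds <- function(outline_a, outline_b, n_resample = 200,
                            allow_mirror = FALSE, max_residual_um = 25,
                            ambiguity_ratio = 2) {
  if (is.null(outline_a) || NROW(outline_a) < 3)
    stop("snick not detected in round A", call. = FALSE)
  if (is.null(outline_b) || NROW(outline_b) < 3)
    stop("snick not detected in round B", call. = FALSE)
  A <- resample_polyline(outline_a, n_resample)
  B <- resample_polyline(outline_b, n_resample)
  cand <- list(
    fwd = kabsch(A, B),
    rev = kabsch(A[n_resample:1, ], B))
  if (allow_mirror) {
    Am <- A; Am[, 1] <- -Am[, 1]
    cand$mir_fwd <- kabsch(Am, B)
    cand$mir_rev <- kabsch(Am[n_resample:1, ], B)
  }
  cand <- Filter(Negate(is.null), cand)
  res <- vapply(cand, `[[`, numeric(1), "rmsd")
  ord <- order(res)
  best <- cand[[ord[1]]]
  if (isTRUE(best$degenerate))
    stop("ambiguous fiducial: outline is degenerate (collinear), orientation unresolved",
         call. = FALSE)
  if (best$rmsd > max_residual_um)
    stop(sprintf("registration failed: best fiducial residual %.1f um exceeds %.1f um",
                 best$rmsd, max_residual_um), call. = FALSE)
  if (length(ord) > 1) {
    second <- res[ord[2]]
    if (second <= ambiguity_ratio * max(best$rmsd, 0.5))
      stop("ambiguous fiducial: two alignments fit comparably (symmetric snick?)",
           call. = FALSE)
  }
  tf <- rigid_transform(best$rotation_deg, best$translation_um,
                        mirror = startsWith(names(cand)[ord[1]], "mir"))
  attr(tf, "residual_um") <- best$rmsd
  tf
}

#' Morphometrics of a nucleus (and its cytoplasm)
#'
#' Measures the cytomorphological quantities the CTC criteria use:
#' equivalent-circle nucleus diameter, nuclear-to-cytoplasmic area ratio
#' (cytoplasm = cell mask minus nucleus), irregularity = 1 - solidity
#' (0 for a convex nucleus), cytoplasm visibility and nucleus integrity
#' (contiguous mask not truncated by the crop border - a heuristic for
#' "well-defined, non-damaged").
#'
#' @param nuclear_mask Logical matrix of the nucleus.
#' @param cell_mask Optional logical matrix of the whole cell (same size).
#'   Omitted: cytoplasm quantities are `NA` and `cytoplasm_present = NA`.
#' @param pixel_size_um Pixel size (um/px).
#' @param min_cytoplasm_frac Cytoplasm counts as "well-defined" when its area
#'   exceeds this fraction of the nuclear area (default 0.2).
#' @return Object of class `morphometrics`: list with `nucleus_diameter_um`,
#'   `nucleus_area_um2`, `nc_ratio`, `irregularity`, `cytoplasm_present`,
#'   `nucleus_intact`.
#' @export
compute_morphometrics <- function(nuclear_mask, cell_mask = NULL,
                                  pixel_size_um = 0.5,
                                  min_cytoplasm_frac = 0.2) {
  if (!any(nuclear_mask)) stop("nuclear mask is empty")
  px <- pixel_size_um
  n_area_px <- sum(nuclear_mask)
  n_area <- n_area_px * px^2
  idx <- which(nuclear_mask, arr.ind = TRUE)
  # solidity: mask pixels over rasterized convex-hull pixels
  hull <- chull(idx[, 2], idx[, 1])
  hx <- idx[hull, 2]; hy <- idx[hull, 1]
  bb_r <- range(idx[, 1]); bb_c <- range(idx[, 2])
  gr <- expand.grid(r = bb_r[1]:bb_r[2], c = bb_c[1]:bb_c[2])
  inhull <- point_in_polygon(gr$c, gr$r, hx, hy)
  hull_px <- sum(inhull)
  irregularity <- clamp(1 - n_area_px / max(hull_px, 1), 0, 1)
  # contiguity + border truncation
  m01 <- matrix(0L, nrow(nuclear_mask), ncol(nuclear_mask))
  m01[nuclear_mask] <- 1L
  ncomp <- attr(.cc_label(m01), "n")
  on_border <- any(nuclear_mask[1, ]) || any(nuclear_mask[nrow(nuclear_mask), ]) ||
    any(nuclear_mask[, 1]) || any(nuclear_mask[, ncol(nuclear_mask)])
  intact <- ncomp == 1L && !on_border
  nc_ratio <- NA_real_; cyt_present <- NA
  if (!is.null(cell_mask)) {
    stopifnot(all(dim(cell_mask) == dim(nuclear_mask)))
    cyt_px <- sum(cell_mask & !nuclear_mask)
    if (cyt_px == 0) {
      cyt_present <- FALSE
      nc_ratio <- Inf
    } else {
      nc_ratio <- n_area_px / cyt_px
      cyt_present <- cyt_px * px^2 > min_cytoplasm_frac * n_area
    }
  }
  structure(
    list(nucleus_diameter_um = equiv_diameter_um(n_area),
         nucleus_area_um2 = n_area, nc_ratio = nc_ratio,
         irregularity = irregularity, cytoplasm_present = cyt_present,
         nucleus_intact = intact),
    class = "morphometrics")
}

# Even-odd point-in-polygon test (vectorized over points).
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i] + 1e-300) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Segment a cytoplasm mask from a brightfield crop
#'
#' Brightfield dye (Mayer-Hemalun or Diff-Quik; the difference is colour
#' metadata only) renders the cell darker than the membrane: the cell mask is
#' the connected region of below-threshold pixels containing the nucleus.
#'
#' @param brightfield A [channel_image()] brightfield crop.
#' @param nuclear_mask Logical matrix (same size).
#' @param k Threshold is `background - k * sd` (default 2).
#' @return Logical cell mask.
#' @export
segment_cytoplasm <- function(brightfield, nuclear_mask, k = 2) {
  stopifnot(inherits(brightfield, "channel_image"),
            all(dim(brightfield$data) == dim(nuclear_mask)))
  img <- brightfield$data
  bg <- median(img); s <- max(mad(img), 1)
  m01 <- matrix(0L, nrow(img), ncol(img))
  m01[img < bg - k * s | nuclear_mask] <- 1L
  lab <- .cc_label(m01)
  hit <- unique(lab[nuclear_mask])
  hit <- hit[hit > 0]
  if (!length(hit)) return(nuclear_mask)
  lab == hit[1]
}

#' Call an epithelial CTC (five criteria)
#'
#' True only if all five hold: (i) well-defined, non-damaged nucleus inside
#' the cytoplasm, (ii) no CD45 expression, (iii) epithelial-marker
#' expression, (iv) nuclear size strictly greater than 1.5 pore diameters
#' (12 um), (v) well-defined cytoplasm. Returns the verdict with the
#' per-criterion breakdown.
#'
#' @param x List/row with fields `nucleus_intact`, `cd45_negative`,
#'   `epithelial_positive`, `nucleus_diameter_um`, `cytoplasm_present`.
#' @return List `call` (logical) and `criteria` (named logical vector
#'   i..v).
#' @export
call_epithelial_ctc <- function(x) {
  need <- c("nucleus_intact", "cd45_negative", "epithelial_positive",
            "nucleus_diameter_um", "cytoplasm_present")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing morphometrics/fields: ", paste(miss, collapse = ", "))
  if (any(vapply(x[need], function(v) is.na(v) || is.null(v), logical(1))))
    stop("missing morphometrics: NA in required fields")
  crit <- c(
    i_nucleus_intact = isTRUE(x$nucleus_intact),
    ii_cd45_negative = isTRUE(x$cd45_negative),
    iii_epithelial_positive = isTRUE(x$epithelial_positive),
    iv_nucleus_gt_12um = x$nucleus_diameter_um > 12,
    v_cytoplasm_present = isTRUE(x$cytoplasm_present))
  list(call = all(crit), criteria = crit)
}

#' Call a marker-negative CTC (cytomorphological criteria)
#'
#' For elements negative for both epithelial and mesenchymal markers:
#' true iff nucleus size of at least two pores (>= 16 um, inclusive),
#' nuclear irregularity at or above `irregularity_min`, and
#' nuclear-to-cytoplasmic ratio at or above `nc_ratio_min`. Note the
#' asymmetric boundary semantics: this rule is inclusive at 16 um while the
#' category split on 16 um is strict - both are honored verbatim where they
#' apply.
#'
#' @param x List/row with `epithelial_positive`, `mesenchymal_positive`,
#'   `nucleus_diameter_um`, `irregularity`, `nc_ratio`.
#' @param irregularity_min Minimum irregularity (1 - solidity), default 0.05.
#' @param nc_ratio_min Minimum N/C ratio, default 2.
#' @return List `call` and `criteria` (named logical vector).
#' @export
call_markerneg_ctc <- function(x, irregularity_min = 0.05, nc_ratio_min = 2) {
  if (isTRUE(x$epithelial_positive) || isTRUE(x$mesenchymal_positive))
    stop("marker-negative rule applied to a marker-positive record", call. = FALSE)
  need <- c("nucleus_diameter_um", "irregularity", "nc_ratio")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing morphometrics: ", paste(miss, collapse = ", "))
  crit <- c(
    i_nucleus_ge_16um = x$nucleus_diameter_um >= 16,
    ii_irregular = x$irregularity >= irregularity_min,
    iii_high_nc_ratio = x$nc_ratio >= nc_ratio_min)
  list(call = all(crit), criteria = crit)
}
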