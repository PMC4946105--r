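# DAPI nucleus segmentation. The scanner's own algorithm is proprietary; the
# re-implementation here mirrors its calibration semantics: an "offset" is
# subtracted to demarcate nuclei from the membrane background, and touching
# nuclei are split (watershed on the distance transform) unless the second,
# no-split pass is requested to form deliberate cluster objects.

#' Segmentation parameters
#'
#' @param offset Threshold in counts: pixels strictly above it are nuclear
#'   foreground. `NULL` picks it automatically as
#'   `background + offset_frac * (p99.5 - background)`, echoing the
#'   "offset as high as possible" calibration intent.
#' @param offset_frac Fraction used by the automatic offset (default 0.3).
#' @param smooth_sigma_um Gaussian pre-smoothing sd (um); 0 disables.
#' @param min_area_um2 Discard components smaller than this (um^2); removes
#'   single-pixel noise, well below any selection gate.
#' @param split Logical: split touching nuclei (watershed). `FALSE` is the
#'   cluster pass where touching nuclei stay one object.
#' @param marker_sep_um Minimum separation between watershed seed maxima (um).
#' @param refine_halfmax Logical: after labeling, re-demarcate each object at
#'   its own half-maximum above background. A single global offset cannot
#'   track cell-to-cell brightness variation; the per-object half-max puts
#'   the boundary at the 50% edge of each nucleus regardless of its peak.
#' @return Object of class `segmentation_params`.
#' @export
segmentation_params <- function(offset = NULL, offset_frac = 0.15,
                                smooth_sigma_um = 0.5, min_area_um2 = 8,
                                split = TRUE, marker_sep_um = 4,
                                refine_halfmax = TRUE) {
  structure(list(offset = offset, offset_frac = offset_frac,
                 smooth_sigma_um = smooth_sigma_um,
                 min_area_um2 = min_area_um2, split = isTRUE(split),
                 marker_sep_um = marker_sep_um,
                 refine_halfmax = isTRUE(refine_halfmax)),
            class = "segmentation_params")
}

#' Segment DAPI-positive nuclei
#'
#' Thresholds the DAPI channel above the (calibrated or automatic) offset,
#' labels 4-connected components, and - in split mode - divides touching
#' nuclei by seeded watershed on the distance transform. Masks are disjoint
#' by construction and each retained mask's mean DAPI exceeds the estimated
#' background.
#'
#' @param dapi A [channel_image()] of the DAPI channel (pixel size required).
#' @param params A [segmentation_params()].
#' @return Object of class `nucleus_segmentation`: list with `labels`
#'   (integer matrix, 0 = background), `n` (object count), `pixel_size_um`,
#'   `offset` (threshold used) and `background` (list `value`, `sd`).
#' @export
segment_nuclei <- function(dapi, params = segmentation_params()) {
  if (!inherits(dapi, "channel_image")) stop("`dapi` must be a channel_image")
  if (is.null(dapi$pixel_size_um) || !is.finite(dapi$pixel_size_um))
    stop("missing pixel size: areas in um^2 are undefined", call. = FALSE)
  px <- dapi$pixel_size_um
  img <- dapi$data
  if (params$smooth_sigma_um > 0)
    img <- .blur_gauss(img, params$smooth_sigma_um / px)
  bg_med <- median(img)
  bg_sd <- mad(img)
  offset <- params$offset
  if (is.null(offset)) {
    # generous initial demarcation: above the noise floor but low enough to
    # catch dim nuclei; per-object half-max refinement sharpens it below
    hi <- as.numeric(quantile(img, 0.995))
    offset <- bg_med + max(params$offset_frac * (hi - bg_med), 4 * bg_sd, 1)
  }
  mask <- matrix(0L, nrow(img), ncol(img))
  mask[img > offset] <- 1L
  lab <- .cc_label(mask)
  n <- attr(lab, "n")
  if (n > 0) {
    # watershed split on the distance transform (always: the half-max
    # refinement below is per-nucleus even when the caller wants merged
    # cluster objects)
    d <- .chamfer_dist(mask)
    ds <- .blur_gauss(d, 1.2)
    rad <- max(1L, as.integer(round(params$marker_sep_um / px / 2)))
    mx <- .max_filter(ds, rad)
    peaks <- matrix(0L, nrow(img), ncol(img))
    peaks[ds >= mx - 1e-9 & mask == 1L & d > 0.5] <- 1L
    markers <- .cc_label(peaks)
    lab <- .watershed_seeded(-ds, markers, mask)
    n <- attr(markers, "n")
  }
  if (n > 0 && params$refine_halfmax) {
    labv <- as.vector(lab)
    fg <- which(labv > 0)
    labf <- labv[fg]
    vals <- as.vector(img)[fg]
    # robust per-object reference level: an upper quantile rather than the
    # max, so a small bright overlap (pore debris, touching brighter cell)
    # cannot drag the half-max above the object's own plateau
    peaks <- vapply(split(vals, labf),
                    function(v) as.numeric(quantile(v, 0.9, names = FALSE)),
                    numeric(1))
    thr <- bg_med + 0.5 * (peaks[as.character(labf)] - bg_med)
    drop <- fg[vals < thr]
    if (length(drop)) lab[drop] <- 0L
  }
  if (n > 0 && !params$split) {
    # cluster pass: touching (refined) nuclei merge into one object
    m2 <- matrix(0L, nrow(lab), ncol(lab))
    m2[lab > 0L] <- 1L
    lab <- .cc_label(m2)
    n <- attr(lab, "n")
  }
  # drop tiny components; keep only masks whose mean DAPI exceeds background
  min_px <- params$min_area_um2 / px^2
  if (n > 0) {
    labv <- as.vector(lab)
    fg <- labv > 0
    labf <- labv[fg]
    sizes <- tabulate(labf, nbins = n)
    sums <- numeric(n)
    s <- rowsum(as.vector(dapi$data)[fg], labf)
    sums[as.integer(rownames(s))] <- s[, 1]
    means <- sums / pmax(sizes, 1)
    keep <- which(sizes >= min_px & means > bg_med)
    relab <- integer(n)
    relab[keep] <- seq_along(keep)
    lab2 <- matrix(0L, nrow(lab), ncol(lab))
    lab2[fg] <- relab[labf]
    lab <- lab2
    n <- length(keep)
  }
  structure(list(labels = lab, n = as.integer(n), pixel_size_um = px,
                 offset = offset, background = list(value = bg_med, sd = bg_sd)),
            class = "nucleus_segmentation")
}

#' @export
print.nucleus_segmentation <- function(x, ...) {
  cat(sprintf("<nucleus_segmentation> %d nuclei, offset %.1f counts, %d x %d px\n",
              x$n, x$offset, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Extract individual masks from a segmentation
#'
#' @param seg A `nucleus_segmentation`.
#' @param ids Which objects (default all).
#' @return Named list of logical matrices (one mask per object).
#' @export
candidate_masks <- function(seg, ids = seq_len(seg$n)) {
  stopifnot(inherits(seg, "nucleus_segmentation"))
  setNames(lapply(ids, function(i) seg$labels == i), paste0("cell_", ids))
}

#' Estimate image background
#'
#' Robust central tendency (median) and spread (MAD) of pixels outside all
#' nuclear masks and outside pore discs, where pore-trapped debris and
#' autofluorescence would otherwise bias the estimate. This is the
#' `Avg_Int_Bg` of the gallery.
#'
#' @param channel A [channel_image()].
#' @param seg Optional `nucleus_segmentation` whose masks are excluded.
#' @param pores Optional data frame of pore centres (`x_um`, `y_um`).
#' @param pore_diameter_um Pore diameter used to carve out pore discs.
#' @return List with `value`, `sd` and `n_pixels`.
#' @export
estimate_background <- function(channel, seg = NULL, pores = NULL,
                                pore_diameter_um = 8) {
  stopifnot(inherits(channel, "channel_image"))
  img <- channel$data
  if (length(img) == 0) stop("image is empty")
  keep <- rep(TRUE, length(img))
  if (!is.null(seg)) keep <- keep & (as.vector(seg$labels) == 0L)
  if (!is.null(pores) && nrow(pores) > 0) {
    px <- channel$pixel_size_um
    nr <- nrow(img); ncl <- ncol(img)
    pore_mask <- matrix(FALSE, nr, ncl)
    r_px <- pore_diameter_um / 2 / px
    for (p in seq_len(nrow(pores))) {
      cx <- pores$x_um[p] / px + 0.5; cy <- pores$y_um[p] / px + 0.5
      xs <- max(1L, floor(cx - r_px)):min(ncl, ceiling(cx + r_px))
      ys <- max(1L, floor(cy - r_px)):min(nr, ceiling(cy + r_px))
      if (!length(xs) || !length(ys)) next
      rr <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
      pore_mask[ys, xs] <- pore_mask[ys, xs] | (rr <= r_px)
    }
    keep <- keep & !as.vector(pore_mask)
  }
  vals <- as.vector(img)[keep]
  if (length(vals) == 0) stop("no background pixels left to estimate from")
  list(value = median(vals), sd = mad(vals), n_pixels = length(vals))
}

#' Measure candidate characteristics
#'
#' Computes, for every segmented object, the gallery characteristics: nuclear
#' area (um^2), equivalent-circle diameter, centroid, mean DAPI (`Avg_Int`),
#' local background (`Avg_Int_Bg`), mean CD45 (`Sec_Avg_Int`), mean
#' epithelial (`Ter_Avg_Int`) and mean mesenchymal (`Quat_Avg_Int`)
#' intensity, plus the on-pore flag when pore metadata is available.
#'
#' @param seg A `nucleus_segmentation`.
#' @param channels Named list of [channel_image()]s with entries `dapi`,
#'   `cd45`, `epithelial`, `mesenchymal` (a `filter_spot` works too).
#' @param background Optional background list per channel (each as returned
#'   by [estimate_background()]); estimated on the fly when omitted.
#' @param pores Optional pore-centre data frame; sets `on_pore` by testing
#'   whether the centroid falls within a pore disc. When absent the flag is NA
#'   ("unknown").
#' @param pore_diameter_um Pore diameter for the on-pore test.
#' @return Data frame of class `cell_candidates`, one row per object.
#' @export
measure_candidates <- function(seg, channels, background = NULL, pores = NULL,
                               pore_diameter_um = 8) {
  stopifnot(inherits(seg, "nucleus_segmentation"))
  if (inherits(channels, "filter_spot")) {
    if (is.null(pores)) pores <- channels$pores
    channels <- channels$channels
  }
  need <- c("dapi", "cd45", "epithelial", "mesenchymal")
  if (!all(need %in% names(channels)))
    stop("channels must include: ", paste(need, collapse = ", "))
  px <- seg$pixel_size_um
  for (ch in need) {
    ci <- channels[[ch]]
    if (!inherits(ci, "channel_image") || !all(dim(ci$data) == dim(seg$labels)) ||
        !isTRUE(all.equal(ci$pixel_size_um, px)))
      stop(sprintf("channel '%s' does not match the segmentation (size or pixel size)", ch))
  }
  if (is.null(background))
    background <- lapply(channels[need], estimate_background, seg = seg,
                         pores = pores, pore_diameter_um = pore_diameter_um)
  n <- seg$n
  if (n == 0) {
    out <- data.frame(id = integer(), centroid_x_um = numeric(),
                      centroid_y_um = numeric(), area_um2 = numeric(),
                      equiv_diameter_um = numeric(), dapi_avg = numeric(),
                      background_avg = numeric(), cd45_avg = numeric(),
                      epithelial_avg = numeric(), mesenchymal_avg = numeric(),
                      on_pore = logical())
    class(out) <- c("cell_candidates", "data.frame")
    attr(out, "pixel_size_um") <- px
    return(out)
  }
  labv <- as.vector(seg$labels)
  fg <- labv > 0
  labf <- labv[fg]
  sizes <- tabulate(labf, nbins = n)
  mean_by <- function(img) {
    s <- rowsum(as.vector(img)[fg], labf)
    as.numeric(s[, 1] / sizes[as.integer(rownames(s))])
  }
  nr <- nrow(seg$labels)
  idx <- which(fg)
  rowpix <- ((idx - 1) %% nr) + 1   # y
  colpix <- ((idx - 1) %/% nr) + 1  # x
  cx <- as.numeric(rowsum(colpix, labf)[, 1] / sizes) - 0.5
  cy <- as.numeric(rowsum(rowpix, labf)[, 1] / sizes) - 0.5
  area <- sizes * px^2
  out <- data.frame(
    id = seq_len(n),
    centroid_x_um = cx * px, centroid_y_um = cy * px,
    area_um2 = area, equiv_diameter_um = equiv_diameter_um(area),
    dapi_avg = mean_by(channels$dapi$data),
    background_avg = background$dapi$value,
    cd45_avg = mean_by(channels$cd45$data),
    epithelial_avg = mean_by(channels$epithelial$data),
    mesenchymal_avg = mean_by(channels$mesenchymal$data),
    on_pore = NA)
  if (!is.null(pores) && nrow(pores) > 0) {
    r2 <- (pore_diameter_um / 2)^2
    out$on_pore <- vapply(seq_len(n), function(i) {
      any((pores$x_um - out$centroid_x_um[i])^2 +
            (pores$y_um - out$centroid_y_um[i])^2 <= r2)
    }, logical(1))
  }
  class(out) <- c("cell_candidates", "data.frame")
  attr(out, "pixel_size_um") <- px
  attr(out, "background") <- background
  out
}
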