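# End-to-end convenience: the first combined assay on one spot image set
# (segmentation in split and cluster passes, background estimation,
# automated DAPI+/CD45- selection, constituent counting, classification,
# gallery).

#' Analyze a filter spot (fluorescence assay)
#'
#' Runs the automated selection and classification pipeline on a four-channel
#' spot: DAPI segmentation twice (splitting touching nuclei for single-cell
#' candidates; without splitting for cluster candidates), background
#' estimation outside masks and pores, candidate measurement, gating,
#' cluster-constituent counting, eight-category classification and gallery
#' construction.
#'
#' Cluster-rule objects that resolve to several split-mode constituents
#' replace those constituents in the output (a cell is reported once, either
#' alone or inside its cluster).
#'
#' @param spot A `filter_spot` (or named list of four [channel_image()]s plus
#'   optional `pores`).
#' @param params [segmentation_params()] for the split pass.
#' @param gates A [selection_gates()] or `NULL` for background-derived gates.
#' @param thresholds A [classification_thresholds()] or `NULL` for
#'   background-derived marker cutoffs.
#' @param margin_um Gallery crop margin.
#' @return List with `candidates`, `selected` (with `category` column),
#'   `gallery`, `gates`, `thresholds`, `background`, `seg_split`,
#'   `seg_cluster`, `constituents`.
#' @export
analyze_spot <- function(spot, params = segmentation_params(), gates = NULL,
                         thresholds = NULL, margin_um = 5) {
  channels <- if (inherits(spot, "filter_spot")) spot$channels else spot
  pores <- if (inherits(spot, "filter_spot")) spot$pores else spot$pores
  params_cluster <- params
  params_cluster$split <- FALSE
  seg_split <- segment_nuclei(channels$dapi, params)
  seg_cluster <- segment_nuclei(channels$dapi, params_cluster)
  bg <- lapply(channels[c("dapi", "cd45", "epithelial", "mesenchymal")],
               estimate_background, seg = seg_cluster, pores = pores)
  if (is.null(gates)) gates <- auto_gates(bg$dapi, bg$cd45)
  if (is.null(thresholds)) thresholds <- auto_thresholds(bg$epithelial, bg$mesenchymal)

  cand_single <- measure_candidates(seg_split, channels, background = bg, pores = pores)
  cand_cluster <- measure_candidates(seg_cluster, channels, background = bg, pores = pores)

  sel_single <- select_cd45_negative(cand_single, gates)
  # the split pass feeds the single-cell path only; large objects that pass
  # the cluster rule without the single rule (CD45+ merged blobs) are the
  # no-split pass's business
  keep_single <- sel_single$dapi_avg >= gates$dapi_min &
    sel_single$cd45_avg <= gates$cd45_max &
    sel_single$area_um2 > gates$area_min_um2
  sel_single <- sel_single[keep_single, , drop = FALSE]
  sel_cluster <- select_cd45_negative(cand_cluster, gates)
  sel_cluster <- sel_cluster[sel_cluster$selection_rule == "cluster-candidate", , drop = FALSE]

  # constituent counts for cluster-rule objects
  constituents <- if (nrow(sel_cluster)) {
    cluster_constituents(seg_cluster, seg_split, channels,
                         cd45_max = gates$cd45_max, ids = sel_cluster$id)
  } else NULL
  # every cluster-rule object is kept (a one-constituent "cluster" is a large
  # nucleus whose CD45 the cluster rule deliberately ignores - e.g. a CTC
  # touching a leukocyte - and falls through to single-cell classification);
  # split-mode singles swallowed by a kept cluster mask are reported once,
  # inside their cluster
  if (nrow(sel_cluster)) {
    labs <- seg_split$labels; labc <- seg_cluster$labels
    swallowed <- unique(unlist(lapply(sel_cluster$id, function(id) {
      v <- labs[labc == id]; unique(v[v > 0])
    })))
    sel_single <- sel_single[!sel_single$id %in% swallowed, , drop = FALSE]
  }
  sel_single$selection_rule <- factor(rep("single", nrow(sel_single)),
                                      levels = levels(sel_single$selection_rule))
  sel_single$source <- rep("split", nrow(sel_single))
  sel_cluster$source <- rep("cluster", nrow(sel_cluster))
  # cluster ids live in the no-split label image; offset them so ids are
  # unique across the combined output (constituent table follows suit)
  id_offset <- 100000L
  if (nrow(sel_cluster)) sel_cluster$id <- sel_cluster$id + id_offset
  if (!is.null(constituents)) constituents$id <- constituents$id + id_offset
  selected <- rbind(sel_single, sel_cluster)

  categories <- classify_candidates(selected, thresholds, constituents)
  selected$category <- categories
  gallery <- build_gallery(selected, categories, channels, margin_um = margin_um)
  list(candidates = cand_single, selected = selected, gallery = gallery,
       gates = gates, thresholds = thresholds, background = bg,
       seg_split = seg_split, seg_cluster = seg_cluster,
       constituents = constituents)
}
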