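# Phenotype classification of selected DAPI+/CD45- elements into the eight
# review categories, and the reviewable image gallery.

#' Classification thresholds
#'
#' @param epithelial_min,mesenchymal_min Marker-positivity cutoffs (counts).
#'   `NULL` = derive from channel background via [auto_thresholds()]
#'   (mean > background + 3 sd).
#' @param two_pore_diameter_um Nucleus-diameter split for marker-negative
#'   cells (default 16 um = two pore diameters); strictly greater-than.
#' @param cluster_min_cells Minimum constituents of a (CTC or mixed) cluster
#'   (default 4).
#' @param microcluster_cells Constituent count of a microcluster (exactly 3).
#' @return Object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(epithelial_min = NULL, mesenchymal_min = NULL,
                                      two_pore_diameter_um = 16,
                                      cluster_min_cells = 4,
                                      microcluster_cells = 3) {
  if (cluster_min_cells <= microcluster_cells)
    stop("cluster_min_cells must exceed microcluster_cells")
  structure(list(epithelial_min = epithelial_min,
                 mesenchymal_min = mesenchymal_min,
                 two_pore_diameter_um = two_pore_diameter_um,
                 cluster_min_cells = cluster_min_cells,
                 microcluster_cells = microcluster_cells),
            class = "classification_thresholds")
}

#' Derive marker-positivity thresholds from background
#'
#' @param background_epithelial,background_mesenchymal Background lists
#'   (`value`, `sd`) from [estimate_background()].
#' @param k Multiplier of the background sd (default 3).
#' @param ... Passed to [classification_thresholds()].
#' @return A [classification_thresholds()] with numeric cutoffs.
#' @export
auto_thresholds <- function(background_epithelial, background_mesenchymal,
                            k = 3, ...) {
  classification_thresholds(
    epithelial_min = background_epithelial$value + k * max(background_epithelial$sd, 1),
    mesenchymal_min = background_mesenchymal$value + k * max(background_mesenchymal$sd, 1),
    ...)
}

#' The review categories
#'
#' The eight categories of selected DAPI+/CD45- elements, plus
#' `"uncategorized-pair"` for objects of exactly two CD45- constituents,
#' which fall between the single-cell and microcluster definitions and are
#' reported explicitly rather than silently binned.
#'
#' @return Character vector of category levels.
#' @export
cell_categories <- function() {
  c("E+/M-", "E+/M+", "E-/M+", "E-/M->2pores", "E-/M-<2pores",
    "CTC-cluster", "mixed-cluster", "microcluster", "uncategorized-pair")
}

#' Classify selected candidates
#'
#' Assigns each selected element exactly one category. Cluster-candidate
#' objects require constituent counts (CD45- and CD45+ nuclei found by
#' re-segmenting the merged mask): four or more constituents of mixed
#' CD45-/CD45+ composition is a mixed cluster; four or more CD45- with no
#' CD45+ is a CTC cluster; exactly three CD45- is a microcluster; exactly two
#' CD45- is reported as an uncategorized pair; a "cluster" that resolves to a
#' single nucleus falls through to the single-cell rules. Single cells split
#' on marker positivity (E/M) and, when both markers are negative, on the
#' equivalent diameter versus two pore diameters (16 um, strictly
#' greater-than: exactly 16 um goes to "<2 pores").
#'
#' @param candidates Selected candidates ([select_cd45_negative()]); a
#'   `selection_rule` column marks cluster candidates.
#' @param thresholds A [classification_thresholds()] with numeric marker
#'   cutoffs (see [auto_thresholds()]).
#' @param constituents Optional data frame `id`, `n_cd45neg`, `n_cd45pos`
#'   giving constituent counts for cluster-candidate rows. Required if any
#'   cluster-candidates are present.
#' @return Factor of categories (levels [cell_categories()]), one per row.
#' @export
classify_candidates <- function(candidates, thresholds, constituents = NULL) {
  stopifnot(inherits(thresholds, "classification_thresholds"))
  if (is.null(thresholds$epithelial_min) || is.null(thresholds$mesenchymal_min))
    stop("thresholds have no numeric marker cutoffs; use auto_thresholds() or set them")
  n <- nrow(candidates)
  rule <- if ("selection_rule" %in% names(candidates))
    as.character(candidates$selection_rule) else rep("single", n)
  out <- character(n)
  for (i in seq_len(n)) {
    if (rule[i] == "cluster-candidate") {
      if (is.null(constituents) || !candidates$id[i] %in% constituents$id)
        stop(sprintf("cluster-candidate id %s has no constituent counts", candidates$id[i]),
             call. = FALSE)
      cc <- constituents[match(candidates$id[i], constituents$id), ]
      k_neg <- cc$n_cd45neg; k_pos <- cc$n_cd45pos
      total <- k_neg + k_pos
      if (total >= thresholds$cluster_min_cells && k_neg >= 1 && k_pos >= 1) {
        out[i] <- "mixed-cluster"; next
      }
      if (k_neg >= thresholds$cluster_min_cells && k_pos == 0) {
        out[i] <- "CTC-cluster"; next
      }
      if (k_neg == thresholds$microcluster_cells) { out[i] <- "microcluster"; next }
      if (k_neg == 2) { out[i] <- "uncategorized-pair"; next }
      # resolves to a single nucleus (or CD45+ remainder): single-cell rules
    }
    e <- candidates$epithelial_avg[i] > thresholds$epithelial_min
    m <- candidates$mesenchymal_avg[i] > thresholds$mesenchymal_min
    out[i] <- if (e && !m) "E+/M-"
      else if (e && m) "E+/M+"
      else if (!e && m) "E-/M+"
      else if (candidates$equiv_diameter_um[i] > thresholds$two_pore_diameter_um)
        "E-/M->2pores" else "E-/M-<2pores"
  }
  factor(out, levels = cell_categories())
}

#' Count cluster constituents by re-segmentation
#'
#' For each cluster-candidate object, re-segments DAPI in split mode within
#' the merged mask, measures each constituent's CD45, and counts CD45- versus
#' CD45+ members (CTC-like constituent = CD45-negative).
#'
#' @param seg_cluster The no-split `nucleus_segmentation` that produced the
#'   cluster candidates.
#' @param seg_split A split-mode `nucleus_segmentation` of the same image.
#' @param channels Channel list (or `filter_spot`) with a `cd45` entry.
#' @param cd45_max CD45 cutoff below/at which a constituent is CD45-negative.
#' @param ids Cluster-candidate object ids in `seg_cluster`.
#' @return Data frame `id`, `n_constituents`, `n_cd45neg`, `n_cd45pos`.
#' @export
cluster_constituents <- function(seg_cluster, seg_split, channels, cd45_max,
                                 ids) {
  if (inherits(channels, "filter_spot")) channels <- channels$channels
  cd45 <- channels$cd45$data
  labc <- seg_cluster$labels
  labs <- seg_split$labels
  out <- lapply(ids, function(id) {
    inmask <- labc == id
    sub <- labs[inmask]
    sub <- sub[sub > 0]
    if (!length(sub))
      return(data.frame(id = id, n_constituents = 0L, n_cd45neg = 0L, n_cd45pos = 0L))
    # constituents = split nuclei with >=50% of their area inside the mask
    cand <- sort(unique(sub))
    sz_in <- tabulate(sub, nbins = max(cand))[cand]
    sz_all <- tabulate(labs[labs > 0], nbins = max(cand))[cand]
    cand <- cand[sz_in >= 0.5 * sz_all]
    if (!length(cand))
      return(data.frame(id = id, n_constituents = 0L, n_cd45neg = 0L, n_cd45pos = 0L))
    mcd <- vapply(cand, function(k) mean(cd45[labs == k]), numeric(1))
    neg <- sum(mcd <= cd45_max)
    data.frame(id = id, n_constituents = length(cand),
               n_cd45neg = as.integer(neg),
               n_cd45pos = as.integer(length(cand) - neg))
  })
  do.call(rbind, out)
}
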