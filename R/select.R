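# Automated DAPI+/CD45- selection. Single cells must pass three criteria -
# DAPI intensity, CD45 intensity, nuclear area strictly greater than 55 um^2
# (one 8-um pore is ~50 um^2). A fourth, cluster criterion selects objects
# with nuclear area strictly greater than 150 um^2 (three pore-equivalents)
# on DAPI alone, CD45 deliberately ignored so mixed CTC/leukocyte clusters
# are not lost.

#' Selection gates for DAPI+/CD45- candidates
#'
#' @param dapi_min Minimum mean DAPI intensity (counts). `NULL` means derive
#'   from background at selection time via [auto_gates()].
#' @param cd45_max Maximum mean CD45 intensity (counts) for the single-cell
#'   rule; ignored by the cluster rule. `NULL` as above.
#' @param area_min_um2 Single-cell nuclear-area gate; strictly greater-than
#'   (default 55 um^2).
#' @param cluster_area_min_um2 Cluster nuclear-area gate; strictly
#'   greater-than (default 150 um^2 = three pore-equivalents).
#' @param pore_area_um2 Reference pore area (um^2), ~50 for an 8-um pore.
#' @return Object of class `selection_gates`.
#' @export
selection_gates <- function(dapi_min = NULL, cd45_max = NULL,
                            area_min_um2 = 55, cluster_area_min_um2 = 150,
                            pore_area_um2 = pi * 4^2) {
  stop_if_not_scalar_num(area_min_um2, "area_min_um2", positive = TRUE)
  stop_if_not_scalar_num(cluster_area_min_um2, "cluster_area_min_um2", positive = TRUE)
  if (cluster_area_min_um2 <= area_min_um2)
    stop("cluster_area_min_um2 must exceed area_min_um2")
  structure(list(dapi_min = dapi_min, cd45_max = cd45_max,
                 area_min_um2 = area_min_um2,
                 cluster_area_min_um2 = cluster_area_min_um2,
                 pore_area_um2 = pore_area_um2),
            class = "selection_gates")
}

#' Derive intensity gates from measured background
#'
#' The assay calibrates intensities rather than fixing counts, so the
#' intensity gates are background-relative: `dapi_min = bg + 5 sd` (nuclei
#' must stand clearly off the membrane) and `cd45_max = bg + 3 sd` (CD45
#' indistinguishable from background).
#'
#' @param background_dapi,background_cd45 Background lists (`value`, `sd`) as
#'   returned by [estimate_background()].
#' @param k_dapi,k_cd45 Multipliers of the background sd.
#' @param ... Passed to [selection_gates()] (area gates).
#' @return A [selection_gates()] with numeric intensity gates.
#' @export
auto_gates <- function(background_dapi, background_cd45,
                       k_dapi = 5, k_cd45 = 3, ...) {
  sd_d <- max(background_dapi$sd, 1)
  sd_c <- max(background_cd45$sd, 1)
  selection_gates(dapi_min = background_dapi$value + k_dapi * sd_d,
                  cd45_max = background_cd45$value + k_cd45 * sd_c, ...)
}

#' Select DAPI+/CD45- candidates
#'
#' Applies the automated selection to measured candidates. Single rule:
#' `dapi_avg >= dapi_min` and `cd45_avg <= cd45_max` and
#' `area_um2 > area_min_um2`. Cluster rule: `area_um2 > cluster_area_min_um2`
#' and `dapi_avg >= dapi_min`, CD45 ignored. The returned rows are exactly the
#' candidates satisfying either rule, in their input order, flagged
#' `"single"` or `"cluster-candidate"` (cluster wins when both rules hold,
#' so the object is re-examined for constituents).
#'
#' @param candidates A `cell_candidates` data frame from
#'   [measure_candidates()].
#' @param gates A [selection_gates()] with numeric `dapi_min` and `cd45_max`
#'   (see [auto_gates()]).
#' @return The selected subset of `candidates` with an additional factor
#'   column `selection_rule` (`"single"` / `"cluster-candidate"`).
#' @export
select_cd45_negative <- function(candidates, gates) {
  stopifnot(inherits(gates, "selection_gates"))
  need <- c("dapi_avg", "cd45_avg", "area_um2")
  if (!all(need %in% names(candidates)))
    stop("candidates are unmeasured: missing ", paste(setdiff(need, names(candidates)), collapse = ", "))
  if (any(!is.finite(as.matrix(candidates[need]))))
    stop("candidates contain non-finite measurements")
  if (is.null(gates$dapi_min) || is.null(gates$cd45_max))
    stop("gates have no numeric intensity cutoffs; use auto_gates() or set them")
  single <- candidates$dapi_avg >= gates$dapi_min &
    candidates$cd45_avg <= gates$cd45_max &
    candidates$area_um2 > gates$area_min_um2
  cluster <- candidates$dapi_avg >= gates$dapi_min &
    candidates$area_um2 > gates$cluster_area_min_um2
  sel <- single | cluster
  out <- candidates[sel, , drop = FALSE]
  out$selection_rule <- factor(ifelse(cluster[sel], "cluster-candidate", "single"),
                               levels = c("single", "cluster-candidate"))
  out
}
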