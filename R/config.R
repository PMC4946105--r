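# Pipeline configuration: every tunable in one validated, JSON-serializable
# object. Lengths are um, areas um^2, exposures ms throughout.

#' Pipeline configuration
#'
#' Bundles the geometry, scan settings, selection gates, classification
#' thresholds, FISH rules and the master seed. Validation happens in the
#' component constructors (exposure 5-100 ms, n_stacks <= 30, positive
#' areas); serialization via [write_config()] / [read_config()] round-trips
#' losslessly.
#'
#' @param geometry A [filter_geometry()].
#' @param scan A [scan_config()].
#' @param gates A [selection_gates()].
#' @param thresholds A [classification_thresholds()].
#' @param rules A [fish_rules()].
#' @param seed Master seed (integer).
#' @param paths Named list of input/output paths (free-form).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(geometry = filter_geometry(), scan = scan_config(),
                            gates = selection_gates(),
                            thresholds = classification_thresholds(),
                            rules = fish_rules(), seed = 1, paths = list()) {
  stopifnot(inherits(geometry, "filter_geometry"), inherits(scan, "scan_config"),
            inherits(gates, "selection_gates"),
            inherits(thresholds, "classification_thresholds"),
            inherits(rules, "fish_rules"))
  structure(list(geometry = geometry, scan = scan, gates = gates,
                 thresholds = thresholds, rules = rules,
                 seed = as.integer(seed), paths = paths),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration (JSON)
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config` a validated
#'   [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  geometry <- filter_geometry(j$geometry$pore_diameter_um, j$geometry$pore_pitch_um,
                              j$geometry$spot_diameter_mm, j$geometry$snick)
  scan <- scan_config(j$scan$n_stacks, j$scan$step_um,
                      as.list(j$scan$exposures_ms), j$scan$gain, j$scan$offset,
                      j$scan$n_focus_points, j$scan$magnification)
  gates <- selection_gates(j$gates$dapi_min, j$gates$cd45_max,
                           j$gates$area_min_um2, j$gates$cluster_area_min_um2,
                           j$gates$pore_area_um2)
  thresholds <- classification_thresholds(
    j$thresholds$epithelial_min, j$thresholds$mesenchymal_min,
    j$thresholds$two_pore_diameter_um, j$thresholds$cluster_min_cells,
    j$thresholds$microcluster_cells)
  rules <- fish_rules(j$rules$signal_diameter_um,
                      j$rules$d_fuse_um / j$rules$signal_diameter_um,
                      j$rules$d_split_um / j$rules$signal_diameter_um)
  pipeline_config(geometry, scan, gates, thresholds, rules,
                  seed = j$seed %||% 1, paths = as.list(j$paths))
}
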