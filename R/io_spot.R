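# Reading and writing spot image sets and z-stacks as multi-page TIFF with a
# JSON ground-truth sidecar. Every output is re-loadable by these readers.

#' Write / read a simulated filter spot
#'
#' `write_spot()` writes one multi-page TIFF (one page per channel, pixel
#' size and exposure in per-page metadata) plus `truth.json` (ground-truth
#' table, pore centres, field size, seed). `read_spot()` restores a
#' `filter_spot` bit-identically.
#'
#' @param spot A `filter_spot`.
#' @param dir Output directory (created).
#' @return `write_spot` returns `dir` invisibly; `read_spot` a `filter_spot`.
#' @export
write_spot <- function(spot, dir) {
  stopifnot(inherits(spot, "filter_spot"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chans <- names(spot$channels)
  pages <- lapply(spot$channels, `[[`, "data")
  desc <- vapply(chans, function(ch) as.character(jsonlite::toJSON(
    list(channel = ch, exposure_ms = spot$channels[[ch]]$exposure_ms,
         pixel_size_um = spot$pixel_size_um), auto_unbox = TRUE)), character(1))
  write_tiff(pages, file.path(dir, "channels.tif"),
             pixel_size_um = spot$pixel_size_um, description = desc)
  jsonlite::write_json(
    list(truth = spot$truth, pores = spot$pores, field_um = spot$field_um,
         pixel_size_um = spot$pixel_size_um, seed = spot$seed,
         exposures_ms = as.list(spot$exposures_ms),
         geometry = unclass(spot$geometry),
         model = unclass(spot$model)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_spot
#' @export
read_spot <- function(dir) {
  tf <- read_tiff(file.path(dir, "channels.tif"))
  meta <- jsonlite::fromJSON(file.path(dir, "truth.json"), simplifyVector = TRUE)
  channels <- lapply(seq_along(tf$pages), function(i) {
    d <- jsonlite::fromJSON(tf$descriptions[i])
    channel_image(tf$pages[[i]], pixel_size_um = d$pixel_size_um,
                  channel = d$channel, exposure_ms = d$exposure_ms)
  })
  names(channels) <- vapply(channels, `[[`, character(1), "channel")
  geometry <- filter_geometry(meta$geometry$pore_diameter_um,
                              meta$geometry$pore_pitch_um,
                              meta$geometry$spot_diameter_mm,
                              meta$geometry$snick)
  model <- exposure_model(meta$model$gain, meta$model$dark_level, meta$model$k,
                          meta$model$read_noise_sd, meta$model$shot_noise)
  structure(
    list(channels = channels, truth = meta$truth, pores = meta$pores,
         geometry = geometry, field_um = meta$field_um,
         pixel_size_um = meta$pixel_size_um, model = model,
         exposures_ms = unlist(meta$exposures_ms), seed = meta$seed),
    class = "filter_spot")
}

#' Write / read a z-stack series
#'
#' One multi-page TIFF, one page per plane, with step, plane height, channel
#' and exposure in per-page JSON metadata.
#'
#' @param zstack A [zstack_series()].
#' @param path TIFF path.
#' @return `write_zstack` returns `path` invisibly; `read_zstack` a
#'   [zstack_series()].
#' @export
write_zstack <- function(zstack, path) {
  stopifnot(inherits(zstack, "zstack_series"))
  n <- n_planes(zstack)
  pages <- lapply(seq_len(n), function(j) zstack$planes[, , j])
  desc <- vapply(seq_len(n), function(j) as.character(jsonlite::toJSON(
    list(channel = zstack$channel, z_um = zstack$z_um[j],
         step_um = zstack$step_um, exposure_ms = zstack$exposure_ms,
         pixel_size_um = zstack$pixel_size_um,
         origin_um = zstack$origin_um), auto_unbox = TRUE)), character(1))
  write_tiff(pages, path, pixel_size_um = zstack$pixel_size_um, description = desc)
  invisible(path)
}

#' @rdname write_zstack
#' @export
read_zstack <- function(path) {
  tf <- read_tiff(path)
  meta <- lapply(tf$descriptions, jsonlite::fromJSON)
  m1 <- meta[[1]]
  zstack_series(tf$pages, step_um = m1$step_um,
                z_um = vapply(meta, `[[`, numeric(1), "z_um"),
                pixel_size_um = m1$pixel_size_um, channel = m1$channel,
                exposure_ms = m1$exposure_ms,
                origin_um = unlist(m1$origin_um))
}
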