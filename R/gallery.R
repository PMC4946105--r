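# The reviewable image gallery: one record per selected element carrying the
# per-channel crops, the five intensity characteristics, area, category and
# review status. Records are immutable once confirmed.

#' Build the image gallery
#'
#' One record per selected element: per-channel crops covering the candidate
#' plus a fixed margin, the measured characteristics (`Avg_Int`,
#' `Avg_Int_Bg`, `Sec_Avg_Int`, `Ter_Avg_Int`, `Quat_Avg_Int`), area and
#' assigned category, with review status `"pending"`.
#'
#' @param selected Selected candidates ([select_cd45_negative()]).
#' @param categories Factor of categories, one per row
#'   ([classify_candidates()]).
#' @param channels Channel list or `filter_spot` with the four channels.
#' @param margin_um Crop margin around the candidate's equivalent radius.
#' @return Object of class `gallery`: list of `gallery_record`s.
#' @export
build_gallery <- function(selected, categories, channels, margin_um = 5) {
  if (inherits(channels, "filter_spot")) channels <- channels$channels
  need <- c("dapi", "cd45", "epithelial", "mesenchymal")
  if (!all(need %in% names(channels)))
    stop("missing channel for crops: ", paste(setdiff(need, names(channels)), collapse = ", "))
  n <- nrow(selected)
  if (length(categories) != n)
    stop("one category per selected element required")
  px <- channels$dapi$pixel_size_um
  dims <- dim(channels$dapi$data)
  recs <- lapply(seq_len(n), function(i) {
    r_um <- selected$equiv_diameter_um[i] / 2 + margin_um
    cx <- selected$centroid_x_um[i] / px
    cy <- selected$centroid_y_um[i] / px
    r_px <- r_um / px
    # half-open pixel window, clipped to the image
    x0 <- max(0L, as.integer(floor(cx - r_px)))
    x1 <- min(dims[2], as.integer(ceiling(cx + r_px)))
    y0 <- max(0L, as.integer(floor(cy - r_px)))
    y1 <- min(dims[1], as.integer(ceiling(cy + r_px)))
    crops <- lapply(channels[need], function(ch)
      ch$data[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE])
    structure(
      list(id = selected$id[i],
           category = as.character(categories[i]),
           area_um2 = selected$area_um2[i],
           avg_int = selected$dapi_avg[i],
           avg_int_bg = selected$background_avg[i],
           sec_avg_int = selected$cd45_avg[i],
           ter_avg_int = selected$epithelial_avg[i],
           quat_avg_int = selected$mesenchymal_avg[i],
           centroid_x_um = selected$centroid_x_um[i],
           centroid_y_um = selected$centroid_y_um[i],
           crop_window = c(x0 = x0, x1 = x1, y0 = y0, y1 = y1),
           crops = crops,
           review_status = "pending"),
      class = "gallery_record")
  })
  structure(recs, class = "gallery", pixel_size_um = px)
}

#' @export
print.gallery <- function(x, ...) {
  cat(sprintf("<gallery> %d records (%s)\n", length(x),
              if (length(x)) paste(names(table(vapply(x, `[[`, "", "category"))),
                                   collapse = ", ") else "empty"))
  invisible(x)
}

#' Gallery as a data frame
#'
#' Scalar characteristics of each record in the column layout of the gallery
#' report: id, category, area_um2, Avg_Int, Avg_Int_Bg, Sec_Avg_Int,
#' Ter_Avg_Int, Quat_Avg_Int, review_status.
#'
#' @param x A `gallery`.
#' @param ... Unused.
#' @return Data frame with one row per record.
#' @export
as.data.frame.gallery <- function(x, ...) {
  if (!length(x))
    return(data.frame(id = integer(), category = character(),
                      area_um2 = numeric(), Avg_Int = numeric(),
                      Avg_Int_Bg = numeric(), Sec_Avg_Int = numeric(),
                      Ter_Avg_Int = numeric(), Quat_Avg_Int = numeric(),
                      centroid_x_um = numeric(), centroid_y_um = numeric(),
                      review_status = character()))
  do.call(rbind, lapply(x, function(r)
    data.frame(id = r$id, category = r$category, area_um2 = r$area_um2,
               Avg_Int = r$avg_int, Avg_Int_Bg = r$avg_int_bg,
               Sec_Avg_Int = r$sec_avg_int, Ter_Avg_Int = r$ter_avg_int,
               Quat_Avg_Int = r$quat_avg_int,
               centroid_x_um = r$centroid_x_um, centroid_y_um = r$centroid_y_um,
               review_status = r$review_status)))
}

#' Write / read the gallery report CSV
#'
#' @param gallery A `gallery` (or its data frame form).
#' @param path CSV path.
#' @return `write_gallery_csv` returns `path` invisibly; `read_gallery_csv`
#'   returns the report data frame.
#' @export
write_gallery_csv <- function(gallery, path) {
  df <- if (inherits(gallery, "gallery")) as.data.frame(gallery) else gallery
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gallery_csv
#' @export
read_gallery_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Flip a record's review status
#'
#' Review is a data operation (the scanner-console step was manual): records
#' move `pending -> confirmed` or `pending -> rejected`; a confirmed record is
#' immutable and refuses further changes.
#'
#' @param gallery A `gallery`.
#' @param id Record id.
#' @param status `"confirmed"` or `"rejected"`.
#' @return The modified gallery.
#' @export
set_review_status <- function(gallery, id, status = c("confirmed", "rejected", "pending")) {
  status <- match.arg(status)
  ids <- vapply(gallery, `[[`, numeric(1), "id")
  k <- match(id, ids)
  if (is.na(k)) stop("no gallery record with id ", id)
  if (gallery[[k]]$review_status == "confirmed" && status != "confirmed")
    stop("record ", id, " is confirmed and immutable")
  gallery[[k]]$review_status <- status
  gallery
}

#' Save / load a gallery with its crops
#'
#' Serializes the full gallery to a directory: the report CSV plus one
#' multi-page TIFF of the four channel crops per record. `load_gallery()`
#' restores identical records.
#'
#' @param gallery A `gallery`.
#' @param dir Directory (created if needed).
#' @return `save_gallery` returns `dir` invisibly; `load_gallery` a `gallery`.
#' @export
save_gallery <- function(gallery, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(gallery)
  win <- if (length(gallery))
    do.call(rbind, lapply(gallery, function(r) as.data.frame(as.list(r$crop_window))))
  else data.frame(x0 = integer(), x1 = integer(), y0 = integer(), y1 = integer())
  write.csv(cbind(df, win), file.path(dir, "gallery.csv"), row.names = FALSE)
  px <- attr(gallery, "pixel_size_um") %||% NA_real_
  for (r in gallery) {
    write_tiff(r$crops, file.path(dir, sprintf("record_%04d.tif", as.integer(r$id))),
               pixel_size_um = px,
               description = jsonlite::toJSON(
                 list(id = r$id, channels = names(r$crops)), auto_unbox = TRUE))
  }
  invisible(dir)
}

#' @rdname save_gallery
#' @export
load_gallery <- function(dir) {
  df <- read.csv(file.path(dir, "gallery.csv"), stringsAsFactors = FALSE)
  recs <- lapply(seq_len(nrow(df)), function(i) {
    tf <- read_tiff(file.path(dir, sprintf("record_%04d.tif", as.integer(df$id[i]))))
    meta <- jsonlite::fromJSON(attr(tf, "description") %||% "{}")
    crops <- setNames(tf$pages, meta$channels)
    structure(
      list(id = df$id[i], category = df$category[i], area_um2 = df$area_um2[i],
           avg_int = df$Avg_Int[i], avg_int_bg = df$Avg_Int_Bg[i],
           sec_avg_int = df$Sec_Avg_Int[i], ter_avg_int = df$Ter_Avg_Int[i],
           quat_avg_int = df$Quat_Avg_Int[i],
           centroid_x_um = df$centroid_x_um[i], centroid_y_um = df$centroid_y_um[i],
           crop_window = c(x0 = df$x0[i], x1 = df$x1[i], y0 = df$y0[i], y1 = df$y1[i]),
           crops = crops, review_status = df$review_status[i]),
      class = "gallery_record")
  })
  structure(recs, class = "gallery", pixel_size_um = NA_real_)
}
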