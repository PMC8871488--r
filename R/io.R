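# File I/O: TIFF cine loops, PNG masks, CSV curve/feature tables, JSON
# fit results and parametric-map export.

#' Write a cine loop as a multi-frame grayscale TIFF
#'
#' Intensities are stored as 32-bit float samples scaled to `[0, 1]` by
#' `scale` (default 255, matching the nominal 0-255 intensity range). TIFF
#' carries no per-frame timestamps; keep them alongside (the cohort manifest
#' written by [write_cohort()] records them) and pass them back to
#' [read_cineloop_tiff()].
#'
#' @param loop a [cine_loop()].
#' @param path output path.
#' @param scale intensity corresponding to sample value 1.0.
#' @return `path`, invisibly.
#' @export
write_cineloop_tiff <- function(loop, path, scale = 255) {
  stopifnot(inherits(loop, "cine_loop"))
  frames <- lapply(seq_len(dim(loop$frames)[1]), function(i) loop$frames[i, , ] / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a multi-frame TIFF as a cine loop
#'
#' RGB frames are converted with [to_luminance()].
#'
#' @param path TIFF path.
#' @param times frame timestamps (s); default: frame index in seconds.
#' @param scale intensity corresponding to sample value 1.0.
#' @param region_tag tag for the loaded loop.
#' @return a [cine_loop()].
#' @export
read_cineloop_tiff <- function(path, times = NULL, scale = 255,
                               region_tag = "RAW") {
  frames <- tiff::readTIFF(path, all = TRUE)
  nt <- length(frames)
  conv <- lapply(frames, function(fr) {
    if (length(dim(fr)) == 3L) to_luminance(fr * scale) else fr * scale
  })
  if (is.null(times)) times <- seq_len(nt) - 1
  arr <- array(0, dim = c(nt, nrow(conv[[1]]), ncol(conv[[1]])))
  for (i in seq_len(nt)) arr[i, , ] <- conv[[i]]
  cine_loop(arr, times, region_tag)
}

#' Read a binary mask from a PNG or single-frame TIFF
#'
#' Any pixel value above 0.5 (on the file's 0-1 scale) is `TRUE`.
#'
#' @param path image path (`.png` or `.tif`/`.tiff`).
#' @param patient_id,class_label forwarded to [roi_mask()].
#' @return an [roi_mask()].
#' @export
read_mask <- function(path, patient_id, class_label) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  roi_mask(img > 0.5, patient_id, class_label)
}

#' Export perfusion curves to CSV
#'
#' Long format: `patient_id, row, col, time_s, intensity`.
#'
#' @param curves result of [extract_curves()].
#' @param path output CSV path.
#' @return the data frame, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  coords <- attr(curves, "coords")
  pid <- attr(curves, "patient_id")
  rows <- lapply(seq_along(curves), function(k) {
    data.frame(patient_id = pid, row = unname(coords[k, 1]),
               col = unname(coords[k, 2]),
               time_s = curves[[k]]$times, intensity = curves[[k]]$intensities,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Serialize a voxel fit table to JSON
#'
#' One record per voxel: coordinates, model kind, parameters, convergence,
#' adjusted R-squared and markers.
#'
#' @param table a `voxel_fit_table` from [fit_roi()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(table, path) {
  fits <- attr(table, "fits")
  recs <- lapply(seq_len(nrow(table)), function(k) {
    f <- fits[[k]]
    list(patient_id = table$patient_id[k], row = table$row[k], col = table$col[k],
         model_kind = f$model_kind, params = f$params, converged = f$converged,
         reason = f$reason, adj_r2 = f$adj_r2,
         markers = as.list(table[k, MARKER_NAMES]))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Export a parametric map
#'
#' Writes a 32-bit float TIFF of the raw marker values (invalid pixels as
#' `NaN`) and an 8-bit RGBA PNG preview using a perceptually ordered
#' colormap (`grDevices::hcl.colors("viridis")`) with invalid pixels fully
#' transparent.
#'
#' @param map a `parametric_map` from [assemble_map()].
#' @param tiff_path,png_path output paths (either may be `NULL` to skip).
#' @return invisible `NULL`.
#' @export
write_map <- function(map, tiff_path = NULL, png_path = NULL) {
  stopifnot(inherits(map, "parametric_map"))
  if (!is.null(tiff_path)) {
    v <- map$values
    v[!map$valid] <- NaN
    rng <- range(v[map$valid], finite = TRUE)
    span <- if (diff(rng) > 0) diff(rng) else 1
    tiff::writeTIFF((v - rng[1]) / span, tiff_path, bits.per.sample = 32L)
  }
  if (!is.null(png_path)) {
    pal <- grDevices::hcl.colors(256, "viridis")
    v <- map$values
    rng <- range(v[map$valid], finite = TRUE)
    span <- if (diff(rng) > 0) diff(rng) else 1
    idx <- pmin(pmax(floor((v - rng[1]) / span * 255) + 1, 1), 256)
    rgb <- grDevices::col2rgb(pal[idx]) / 255
    h <- nrow(v); w <- ncol(v)
    img <- array(0, dim = c(h, w, 4))
    img[, , 1] <- matrix(rgb[1, ], h, w)
    img[, , 2] <- matrix(rgb[2, ], h, w)
    img[, , 3] <- matrix(rgb[3, ], h, w)
    img[, , 4] <- ifelse(map$valid, 1, 0)
    img[is.na(img)] <- 0
    png::writePNG(img, png_path)
  }
  invisible(NULL)
}

#' Export an mRMR selection report as JSON
#'
#' @param selection result of [mrmr_select()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(selection, path) {
  jsonlite::write_json(
    list(ranked = as.character(selection),
         objective = as.numeric(attr(selection, "scores")),
         relevance = as.list(attr(selection, "relevance"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
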