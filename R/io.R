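# Slide storage: one multi-page 32-bit float TIFF per slide (one page per
# channel) plus a JSON sidecar carrying channel names, per-channel scale,
# pixel size and identifiers; ground truth and call tables as CSV.

#' Write / read a slide as multi-page TIFF plus JSON sidecar
#'
#' Channels are stored one per TIFF page as 32-bit floats normalized by a
#' per-channel scale recorded in the sidecar (`<path>.json`), giving an
#' exact round trip.
#'
#' @param slide a `slide_image`.
#' @param path TIFF file path (sidecar written next to it).
#' @return `read_slide()` returns the `slide_image`.
#' @export
write_slide <- function(slide, path) {
  scales <- vapply(slide$channels, function(m) max(max(m), 1), numeric(1))
  pages <- mapply(function(m, s) m / s, slide$channels, scales, SIMPLIFY = FALSE)
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    channels = names(slide$channels), scales = as.list(scales),
    pixel_size = slide$pixel_size,
    slide_id = slide$slide_id, sample_id = slide$sample_id,
    operator_id = slide$operator_id, run_id = slide$run_id,
    test_id = slide$test_id, metadata = slide$metadata
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_slide
#' @export
read_slide <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar)) {
    ctc_error("ctcscope_input_error", sprintf("missing slide file or sidecar: %s", path))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(meta$channels)) {
    ctc_error("ctcscope_input_error", "TIFF page count does not match sidecar channels")
  }
  ch <- mapply(function(p, s) p * s, pages, unlist(meta$scales), SIMPLIFY = FALSE)
  names(ch) <- meta$channels
  structure(list(
    channels = ch, pixel_size = meta$pixel_size,
    slide_id = meta$slide_id, sample_id = meta$sample_id,
    operator_id = meta$operator_id, run_id = meta$run_id,
    test_id = meta$test_id, metadata = meta$metadata
  ), class = "slide_image")
}

#' Write a dataset (slides, truth, manifest) to a directory
#'
#' @param dataset a `slide_dataset` from the generators.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (entry in dataset$slides) {
    base <- file.path(dir, entry$slide$slide_id)
    write_slide(entry$slide, paste0(base, ".tif"))
    truth <- entry$truth
    truth$neighbour_ids <- NULL
    write.csv(truth, paste0(base, "_truth.csv"), row.names = FALSE)
  }
  write.csv(dataset$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(list(n_slides = length(dataset$slides)),
                       file.path(dir, "dataset.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Write per-cell call tables as CSV
#'
#' Flattens the cell features and calls of a `slide_result` into one CSV
#' (cell_id, centroid, morphometrics, channel means, gates, call,
#' cluster_id).
#'
#' @param result a `slide_result`.
#' @param path CSV path.
#' @export
write_call_table <- function(result, path) {
  if (is.null(result$cells)) {
    write.csv(data.frame(), path, row.names = FALSE)
    return(invisible(path))
  }
  cells <- result$cells
  cells$neighbour_ids <- vapply(cells$neighbour_ids, paste, character(1),
                                collapse = ";")
  out <- merge(cells, result$calls, by = "cell_id")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export a candidate review gallery
#'
#' Writes one PNG per CTC candidate: a channel montage (DAPI | CK | CD45
#' [| M4]) cropped around the cell, named by call and cell id. A
#' non-interactive stand-in for technician review.
#'
#' @param slide a `slide_image`.
#' @param result its `slide_result`.
#' @param dir output directory.
#' @param crop_um half-width of the crop, microns.
#' @return paths written, invisibly.
#' @export
export_gallery <- function(slide, result, dir, crop_um = 20) {
  if (!requireNamespace("png", quietly = TRUE)) {
    ctc_error("ctcscope_input_error", "the png package is required for gallery export")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(result$calls)) return(invisible(character(0)))
  cand <- result$calls$cell_id[result$calls$call %in% CTC_CLASSES]
  r <- round(crop_um / slide$pixel_size)
  paths <- character(0)
  for (id in cand) {
    cx <- round(result$cells$x[id]) + 1; cy <- round(result$cells$y[id]) + 1
    h <- nrow(slide$channels[[1]]); w <- ncol(slide$channels[[1]])
    ys <- max(1, cy - r):min(h, cy + r)
    xs <- max(1, cx - r):min(w, cx + r)
    crops <- lapply(slide$channels, function(m) {
      c0 <- m[ys, xs]; c0 / max(c0, 1)
    })
    montage <- do.call(cbind, crops)
    p <- file.path(dir, sprintf("%s_cell%04d_%s.png", result$slide_id, id,
                                result$calls$call[result$calls$cell_id == id]))
    png::writePNG(montage, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
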