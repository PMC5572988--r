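# Nucleated-cell detection and feature extraction. Recipe: Gaussian
# smoothing -> global Otsu threshold on DAPI (floored at background median
# + k MADs so blank rasters yield no foreground) -> hole filling ->
# distance-transform watershed declumping -> apoptotic fragment grouping ->
# minimum-area filter. All physical thresholds are in microns and converted
# through the slide pixel size.

smooth_channel <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  imageData(filter2(Image(m), gaussian_kernel(sigma_px), boundary = "replicate"))
}

# global foreground mask with a robust floor under the Otsu threshold
foreground_mask <- function(m, sigma_px, k) {
  sm <- smooth_channel(m, sigma_px)
  lo <- min(sm); hi <- max(sm)
  if (hi - lo < .Machine$double.eps) return(matrix(FALSE, nrow(m), ncol(m)))
  thr_otsu <- otsu(Image((sm - lo) / (hi - lo)), range = c(0, 1)) * (hi - lo) + lo
  thr <- max(thr_otsu, median(sm) + k * mad(sm))
  sm > thr
}

#' Detect nuclei on a slide
#'
#' Segments the DAPI channel into disjoint nuclear masks, declumps touching
#' nuclei with a distance-transform watershed, and groups apoptotic nuclear
#' fragments (small components that fall within a grouping radius of each
#' other and share one connected CK-positive cytoplasm) into single cells.
#'
#' @param slide a `slide_image`.
#' @param params a [segmentation_params()].
#' @return object of class `nuclei_masks`: list with `labels` (integer
#'   matrix, one id per cell, 0 = background), `n` (cell count) and
#'   `fragment_count` (per-cell nuclear fragment count).
#' @export
detect_nuclei <- function(slide, params = segmentation_params()) {
  if (is.null(slide$channels$DAPI)) {
    ctc_error("ctcscope_input_error", "slide has no DAPI channel")
  }
  px <- slide$pixel_size
  dapi <- slide$channels$DAPI
  mask <- foreground_mask(dapi, params$smooth_sigma / px, params$threshold_k)
  empty <- structure(list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                          n = 0L, fragment_count = integer(0)),
                     class = "nuclei_masks")
  if (!any(mask)) return(empty)
  mask <- imageData(fillHull(Image(mask * 1)))
  L <- imageData(watershed(distmap(Image(mask)),
                           tolerance = params$watershed_tolerance / px, ext = 1))
  storage.mode(L) <- "integer"
  ncomp <- max(L)
  if (ncomp == 0L) return(empty)

  idx <- which(L > 0L)
  lab <- L[idx]
  area_px <- tabulate(lab, ncomp)
  h <- nrow(L)
  row <- ((idx - 1L) %% h) + 1L
  col <- ((idx - 1L) %/% h) + 1L
  cy <- rowsum(as.numeric(row), lab)[, 1] / area_px
  cx <- rowsum(as.numeric(col), lab)[, 1] / area_px
  area_um2 <- area_px * px^2

  # ---- apoptotic fragment grouping ----
  parent <- seq_len(ncomp)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  eligible <- which(area_um2 <= params$fragment_area_max)
  if (length(eligible) >= 2 && !is.null(slide$channels$CK)) {
    ck_mask <- foreground_mask(slide$channels$CK, params$smooth_sigma / px,
                               params$threshold_k)
    ck_lab <- imageData(bwlabel(Image(ck_mask * 1)))
    at <- function(i) {
      r <- pmin(pmax(round(cy[i]), 1), nrow(ck_lab))
      c <- pmin(pmax(round(cx[i]), 1), ncol(ck_lab))
      ck_lab[cbind(r, c)]
    }
    ckl <- at(eligible)
    grp_r <- params$grouping_radius / px
    keep <- ckl > 0
    el <- eligible[keep]; elck <- ckl[keep]
    if (length(el) >= 2) {
      for (a in seq_len(length(el) - 1)) {
        for (b in (a + 1):length(el)) {
          if (elck[a] == elck[b] &&
              sqrt((cx[el[a]] - cx[el[b]])^2 + (cy[el[a]] - cy[el[b]])^2) <= grp_r) {
            ra <- find(el[a]); rb <- find(el[b])
            if (ra != rb) parent[rb] <- ra
          }
        }
      }
    }
  }
  root <- vapply(seq_len(ncomp), find, integer(1))
  group_area <- rowsum(area_um2, root)
  groups <- as.integer(rownames(group_area))
  keep_groups <- groups[group_area[, 1] >= params$min_nuclear_area]
  if (!length(keep_groups)) return(empty)

  new_id <- integer(ncomp)
  new_id[keep_groups] <- seq_along(keep_groups)
  cell_of_comp <- new_id[root]           # 0 = dropped
  frag <- tabulate(cell_of_comp[cell_of_comp > 0L], length(keep_groups))

  L2 <- matrix(0L, nrow(L), ncol(L))
  L2[idx] <- cell_of_comp[lab]
  structure(list(labels = L2, n = length(keep_groups), fragment_count = frag),
            class = "nuclei_masks")
}

#' Extract per-cell morphometric and intensity features
#'
#' Computes, for every nuclear mask group, its area, equivalent diameter,
#' solidity and fragment count, plus background-subtracted channel means:
#' DAPI over the nucleus, markers (CK/CD45/M4) over a cytoplasm ring formed
#' by dilating the nucleus and clipping against neighbouring cells
#' (nearest-nucleus partition). Background per channel is the median of
#' pixels outside all dilated cells; its MAD is kept for noise floors.
#'
#' @param slide a `slide_image`.
#' @param masks a `nuclei_masks` from [detect_nuclei()].
#' @param params a [segmentation_params()].
#' @return data.frame of class `cell_features`, one row per cell:
#'   `cell_id`, `x`, `y` (0-based pixel centroid), `nuclear_area_um2`,
#'   `equivalent_diameter_um`, `solidity`, `fragment_count`, `dapi_mean`,
#'   `ck_mean`, `cd45_mean`, `m4_mean`, `ring_px`, and list column
#'   `neighbour_ids`. Attributes: `pixel_size`, `background` (per-channel
#'   median), `background_mad`.
#' @export
extract_features <- function(slide, masks, params = segmentation_params()) {
  stopifnot(inherits(masks, "nuclei_masks"))
  L <- masks$labels
  if (!all(dim(L) == dim(slide$channels$DAPI))) {
    ctc_error("ctcscope_input_error", "mask does not match raster bounds")
  }
  px <- slide$pixel_size
  n <- masks$n
  chans <- slide$channels
  have <- names(chans)
  empty <- data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                      nuclear_area_um2 = numeric(0),
                      equivalent_diameter_um = numeric(0), solidity = numeric(0),
                      fragment_count = integer(0), dapi_mean = numeric(0),
                      ck_mean = numeric(0), cd45_mean = numeric(0),
                      m4_mean = numeric(0), ring_px = integer(0))
  if (n == 0L) {
    empty$neighbour_ids <- list()
    class(empty) <- c("cell_features", "data.frame")
    attr(empty, "pixel_size") <- px
    return(empty)
  }
  h <- nrow(L)
  ring_px_r <- max(1L, round(params$ring_width / px))
  brush <- makeBrush(2L * ring_px_r + 1L, "disc")
  dil <- imageData(dilate(Image((L > 0L) * 1), brush)) > 0

  # cytoplasm: nearest-nucleus partition of the dilated zone
  cyto <- imageData(propagate(Image(matrix(0, nrow(L), ncol(L))),
                              seeds = Image(L), mask = Image(dil * 1)))
  storage.mode(cyto) <- "integer"

  bg <- sapply(have, function(nm) median(chans[[nm]][!dil]))
  bg_mad <- sapply(have, function(nm) mad(chans[[nm]][!dil]))

  idx <- which(L > 0L)
  lab <- L[idx]
  area_px <- tabulate(lab, n)
  row <- ((idx - 1L) %% h) + 1L
  col <- ((idx - 1L) %/% h) + 1L
  cy <- rowsum(as.numeric(row), lab)[, 1] / area_px
  cx <- rowsum(as.numeric(col), lab)[, 1] / area_px

  # solidity: mask area over (convex hull area, pixel-corrected), clamped to 1
  solidity <- vapply(split(seq_along(lab), lab), function(ii) {
    pts <- cbind(col[ii], row[ii])
    if (nrow(pts) < 4) return(1)
    hull <- pts[chull(pts), , drop = FALSE]
    if (nrow(hull) < 3) return(1)
    xh <- hull[, 1]; yh <- hull[, 2]
    a2 <- abs(sum(xh * c(yh[-1], yh[1]) - c(xh[-1], xh[1]) * yh)) / 2
    per <- sum(sqrt(diff(c(xh, xh[1]))^2 + diff(c(yh, yh[1]))^2))
    min(1, nrow(pts) / (a2 + per / 2 + 1))
  }, numeric(1))

  nuc_mean <- function(nm) {
    rowsum(chans[[nm]][idx], lab)[, 1] / area_px - bg[[nm]]
  }
  # ring = cytoplasm partition minus all nuclei
  ridx <- which(cyto > 0L & L == 0L)
  rlab <- cyto[ridx]
  ring_n <- tabulate(rlab, n)
  ring_mean <- function(nm) {
    s <- rep(0, n)
    rs <- rowsum(chans[[nm]][ridx], rlab)
    s[as.integer(rownames(rs))] <- rs[, 1]
    out <- ifelse(ring_n > 0, s / pmax(ring_n, 1L), NA_real_) - bg[[nm]]
    # fallback: fully enclosed cell measures markers over its nucleus
    fb <- ring_n == 0
    if (any(fb)) out[fb] <- nuc_mean(nm)[fb]
    out
  }

  cells <- data.frame(
    cell_id = seq_len(n),
    x = cx - 1, y = cy - 1,
    nuclear_area_um2 = area_px * px^2,
    equivalent_diameter_um = 2 * sqrt(area_px * px^2 / pi),
    solidity = solidity,
    fragment_count = masks$fragment_count,
    dapi_mean = nuc_mean("DAPI"),
    ck_mean = if ("CK" %in% have) ring_mean("CK") else NA_real_,
    cd45_mean = if ("CD45" %in% have) ring_mean("CD45") else NA_real_,
    m4_mean = if ("M4" %in% have) ring_mean("M4") else NA_real_,
    ring_px = ifelse(ring_n > 0L, ring_n, area_px)
  )

  # neighbour pairs: 8-connectivity adjacency of the cytoplasm partition
  pairs <- rbind(
    cbind(as.vector(cyto[-1, ]), as.vector(cyto[-nrow(cyto), ])),
    cbind(as.vector(cyto[, -1]), as.vector(cyto[, -ncol(cyto)])),
    cbind(as.vector(cyto[-1, -1]), as.vector(cyto[-nrow(cyto), -ncol(cyto)])),
    cbind(as.vector(cyto[-1, -ncol(cyto)]), as.vector(cyto[-nrow(cyto), -1]))
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(cbind(pmin(pairs[, 1], pairs[, 2]),
                          pmax(pairs[, 1], pairs[, 2])))
  }
  nb <- vector("list", n)
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  cells$neighbour_ids <- lapply(nb, function(v) sort(unique(v)))

  class(cells) <- c("cell_features", "data.frame")
  attr(cells, "pixel_size") <- px
  attr(cells, "background") <- bg
  attr(cells, "background_mad") <- bg_mad
  cells
}

#' Build the slide-internal WBC reference
#'
#' Gates cells on a provisional CD45-positivity rule (CD45 mean above half
#' the upper-quartile population level and above the pixel-noise floor;
#' valid because WBCs dominate every slide by orders of magnitude) and
#' summarizes the CD45+ population: median nuclear diameter and area, and
#' per-channel robust level/spread used as the marker-gate null.
#'
#' @param cells a `cell_features` data.frame.
#' @param thresholds a [classifier_thresholds()]; `min_wbc` is the minimum
#'   number of CD45+ cells required.
#' @return object of class `wbc_reference`.
#' @export
estimate_wbc_reference <- function(cells, thresholds = classifier_thresholds()) {
  bg_mad <- attr(cells, "background_mad")
  sigma_cell <- if (!is.null(bg_mad) && "CD45" %in% names(bg_mad)) {
    bg_mad[["CD45"]] / sqrt(pmax(cells$ring_px, 1))
  } else rep(0, nrow(cells))
  prov <- cells$cd45_mean > pmax(0.5 * quantile(cells$cd45_mean, 0.75, na.rm = TRUE),
                                 5 * sigma_cell)
  prov[is.na(prov)] <- FALSE
  if (sum(prov) < thresholds$min_wbc) {
    ctc_error("ctcscope_reference_failure",
              sprintf("only %d CD45+ cells found; >= %d required to build a WBC reference",
                      sum(prov), thresholds$min_wbc))
  }
  w <- cells[prov, ]
  neg <- cells[!prov, ]
  sigma_floor <- median(if (!is.null(bg_mad)) {
    unlist(bg_mad[c("CK", "CD45")]) / sqrt(median(pmax(cells$ring_px, 1)))
  } else 0)
  cd45_med <- median(w$cd45_mean)
  cd45_thr <- if (nrow(neg) > 0) {
    min(median(neg$cd45_mean) + thresholds$k * max(mad(neg$cd45_mean), sigma_floor),
        0.5 * cd45_med)
  } else 0.5 * cd45_med
  structure(list(
    n_wbc = nrow(w),
    median_diameter_um = median(w$equivalent_diameter_um),
    median_area_um2 = median(w$nuclear_area_um2),
    median_dapi = median(w$dapi_mean),
    ck_level = median(w$ck_mean),
    ck_mad = max(mad(w$ck_mean), sigma_floor),
    cd45_level = cd45_med,
    cd45_threshold = cd45_thr,
    sigma_floor = sigma_floor
  ), class = "wbc_reference")
}

#' @export
print.wbc_reference <- function(x, ...) {
  cat(sprintf("<wbc_reference> %d CD45+ cells; median nuclear diameter %.2f um\n",
              x$n_wbc, x$median_diameter_um))
  invisible(x)
}
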