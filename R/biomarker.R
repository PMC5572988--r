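# Single-cell biomarker analyses: fourth-channel protein quantitation and
# two-colour FISH signal counting with PTEN/CEP10 deletion-status calling.

#' Quantify fourth-channel marker expression per cell
#'
#' Reports the background-subtracted mean intensity of the open marker
#' channel per cell, population-relative z-scores, and group medians when
#' group labels are supplied (e.g. comparing high/medium/low expressing
#' cell lines).
#'
#' @param cells a `cell_features` data.frame.
#' @param channel feature column holding the marker mean (default
#'   `"m4_mean"`).
#' @param groups optional factor/character of group labels per cell.
#' @return data.frame `cell_id`, `expression`, `z`, and (if groups given)
#'   `group`; attribute `group_medians` is a named vector of group medians.
#' @export
quantify_marker <- function(cells, channel = "m4_mean", groups = NULL) {
  if (!channel %in% names(cells) || all(is.na(cells[[channel]]))) {
    ctc_error("ctcscope_input_error",
              sprintf("marker channel '%s' is not available", channel))
  }
  expr <- cells[[channel]]
  s <- sd(expr)
  z <- if (is.na(s) || s == 0) rep(0, length(expr)) else (expr - mean(expr)) / s
  out <- data.frame(cell_id = cells$cell_id, expression = expr, z = z)
  if (!is.null(groups)) {
    stopifnot(length(groups) == nrow(cells))
    out$group <- as.character(groups)
    attr(out, "group_medians") <- c(tapply(expr, as.character(groups), median))
  }
  out
}

# ---- FISH -----------------------------------------------------------------

#' Count punctate FISH signals inside a nucleus
#'
#' Laplacian-of-Gaussian blob detection: the patch is convolved with a
#' scale-normalized LoG kernel matched to the expected spot size; local
#' maxima of the response inside the nuclear mask exceeding a prominence
#' threshold (relative to the robust background spread) are counted, with
#' greedy non-maximum suppression at one spot radius. Two spots closer than
#' about twice the spot sigma merge into one response peak; that is the
#' resolution limit of the detector.
#'
#' @param patch 2-D intensity matrix of one FISH colour channel.
#' @param mask logical or 0/1 matrix of the nucleus, same shape as `patch`.
#' @param spot_sigma expected spot Gaussian sigma, microns.
#' @param pixel_size microns per pixel of the patch.
#' @param prominence_k minimum peak response in units of the robust spread
#'   of the response outside the mask.
#' @return integer signal count.
#' @export
count_fish_signals <- function(patch, mask, spot_sigma = 0.25,
                               pixel_size = 0.2, prominence_k = 8) {
  if (!all(dim(mask) == dim(patch))) {
    ctc_error("ctcscope_input_error", "mask must match patch dimensions")
  }
  mask <- mask > 0
  if (!any(mask)) ctc_error("ctcscope_input_error", "empty nucleus mask")
  s <- spot_sigma / pixel_size
  r <- max(2L, ceiling(4 * s))
  g <- seq(-r, r)
  d2 <- outer(g^2, g^2, "+")
  log_k <- (d2 - 2 * s^2) / s^4 * exp(-d2 / (2 * s^2))
  log_k <- log_k - mean(log_k)
  resp <- -imageData(filter2(Image(patch), log_k, boundary = "replicate")) * s^2

  out_bg <- resp[!mask]
  thr <- median(out_bg) + prominence_k * max(mad(out_bg), .Machine$double.eps)

  # local maxima over a 3x3 neighbourhood
  h <- nrow(resp); w <- ncol(resp)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- resp
  is_max <- matrix(TRUE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    is_max <- is_max & (resp >= pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)])
  }
  cand <- which(is_max & mask & resp > thr)
  if (!length(cand)) return(0L)
  ry <- ((cand - 1L) %% h) + 1L
  rx <- ((cand - 1L) %/% h) + 1L
  o <- order(resp[cand], decreasing = TRUE)
  min_sep <- 2 * s
  keep_x <- numeric(0); keep_y <- numeric(0)
  for (i in o) {
    if (!length(keep_x) ||
        all((keep_x - rx[i])^2 + (keep_y - ry[i])^2 >= min_sep^2)) {
      keep_x <- c(keep_x, rx[i]); keep_y <- c(keep_y, ry[i])
    }
  }
  length(keep_x)
}

#' Render a synthetic FISH patch
#'
#' Gaussian spots on a DAPI-like nuclear disc; used as ground-truth oracle
#' for the spot counter.
#'
#' @param shape patch (h, w) in pixels.
#' @param spots data.frame with 0-based `x`, `y` and optional `amp`.
#' @param spot_sigma spot sigma, microns.
#' @param pixel_size microns per pixel.
#' @param nucleus_radius nucleus radius, microns (centred disc).
#' @param background,noise_sd additive background and read-noise SD.
#' @param seed integer seed.
#' @return list with `patch` (spot channel), `mask` (nucleus disc).
#' @export
render_fish_patch <- function(shape = c(64, 64), spots,
                              spot_sigma = 0.25, pixel_size = 0.2,
                              nucleus_radius = 4, background = 50,
                              noise_sd = 2, seed = 1L) {
  h <- shape[1]; w <- shape[2]
  s <- spot_sigma / pixel_size
  patch <- matrix(0, h, w)
  with_seed(seed, {
    if (nrow(spots)) {
      for (i in seq_len(nrow(spots))) {
        a <- if ("amp" %in% names(spots)) spots$amp[i] else 200
        xs <- 1:w; ys <- 1:h
        patch <- patch + a * exp(-(outer((ys - 1 - spots$y[i])^2,
                                         (xs - 1 - spots$x[i])^2, "+")) / (2 * s^2))
      }
    }
    patch <- patch + background
    if (noise_sd > 0) patch <- patch + matrix(rnorm(h * w, 0, noise_sd), h, w)
  })
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  rpx <- nucleus_radius / pixel_size
  mask <- outer((1:h - 1 - cy)^2, (1:w - 1 - cx)^2, "+") <= rpx^2
  list(patch = patch, mask = mask)
}

#' Call PTEN deletion status from two-colour FISH counts
#'
#' PTEN (gene probe) versus CEP10 (chromosome-10 centromere reference):
#' zero PTEN signals is homozygous loss; fewer PTEN than CEP10 signals is
#' heterozygous loss; PTEN at or above CEP10 is non-deleted. More than two
#' CEP10 signals flags polyploidy. A cell with zero signals in both colours
#' is uncountable and reported as NA rather than a loss call.
#'
#' @param pten,cep10 non-negative integer signal counts (vectorized).
#' @return data.frame `pten`, `cep10`, `status` (factor: `NON_DELETED`,
#'   `HETEROZYGOUS_LOSS`, `HOMOZYGOUS_LOSS`, or NA when uncountable) and
#'   logical `polyploid`.
#' @export
#' @examples
#' classify_pten_status(c(3, 2, 0), c(3, 4, 4))
classify_pten_status <- function(pten, cep10) {
  if (any(pten < 0) || any(cep10 < 0)) {
    ctc_error("ctcscope_input_error", "signal counts must be >= 0")
  }
  status <- ifelse(pten == 0 & cep10 == 0, NA_character_,
            ifelse(pten == 0, "HOMOZYGOUS_LOSS",
            ifelse(pten < cep10, "HETEROZYGOUS_LOSS", "NON_DELETED")))
  data.frame(
    pten = pten, cep10 = cep10,
    status = factor(status, levels = c("NON_DELETED", "HETEROZYGOUS_LOSS",
                                       "HOMOZYGOUS_LOSS")),
    polyploid = cep10 > 2
  )
}
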