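#' Configuration for the synthetic slide generator
#'
#' Builds and validates the full parameter set used to render synthetic
#' immunofluorescent slide tiles. A "slide" is represented at desk scale by
#' a single tile carrying `wbc_count` white blood cells (default 5000),
#' standing in for the 3e6 nucleated cells a physical slide carries; the
#' scale factor is recorded in every slide's metadata so per-slide
#' statistics stay scale-free.
#'
#' @param tile_shape integer (height, width) of the tile in pixels.
#' @param pixel_size microns per pixel (10X-like sampling by default).
#' @param wbc_count nucleated background cells nominally deposited per tile.
#' @param wbc_nuclear_diameter,clc_nuclear_diameter c(mean, sd) nuclear
#'   diameters in microns; cell-line control (CLC) nuclei are larger than
#'   WBC nuclei.
#' @param small_nuclear_diameter c(mean, sd) in microns for the small-CTC
#'   subtype (at or below typical WBC nuclear size).
#' @param background_level,noise_sd per-channel additive background and
#'   Gaussian read-noise SD, in intensity units.
#' @param shot_noise logical; add Poisson shot noise on top of read noise.
#' @param psf_sigma point-spread-function sigma in microns (Gaussian blur).
#' @param amplitudes named list of mean signal amplitudes above background:
#'   `dapi`, `ck`, `cd45`, `m4`. Per-cell amplitudes vary with
#'   `amplitude_cv` relative SD.
#' @param amplitude_cv relative SD of per-cell amplitude variation.
#' @param ring_width cytoplasm halo width beyond the nuclear radius, microns.
#' @param deposition_retention probability in \[0,1\] that a deposited
#'   nucleated cell is retained on the slide. The default 0.88 reflects the
#'   typical measured nucleated-cell recovery of the deposition process.
#' @param spiking_mode one of `"deterministic"`, `"binomial"`, `"poisson"`.
#'   Deterministic mode places exactly `n_clc` CLCs (a verified spike
#'   count); the stochastic modes draw the retained count with success /
#'   rate parameter `n_clc * deposition_retention`.
#' @param subtype_mix named proportions over
#'   `traditional`, `small`, `cluster`, `ck_negative`, `apoptotic`; must sum
#'   to 1. The default is all-traditional, matching an epithelial cell-line
#'   control spike.
#' @param debris_rate expected count per tile of CK-positive acellular
#'   debris objects (no nucleus); exercises specificity.
#' @param speckle_rate expected count per tile of sub-cellular DAPI speckle
#'   artifacts.
#' @param m4_enabled render a fourth marker channel `M4`.
#' @param m4_amplitude mean M4 amplitude applied to CLCs (0 disables signal).
#' @param ml_per_slide millilitres of blood represented by one slide
#'   (10 mL tube over up to 12 slides by default).
#' @param seed master integer seed; per-slide child seeds are derived
#'   deterministically from it.
#'
#' @return object of class `generator_config` (a validated list).
#' @export
#' @examples
#' cfg <- generator_config(tile_shape = c(512, 512), wbc_count = 300)
#' cfg$scale_factor
generator_config <- function(tile_shape = c(1600L, 1600L),
                             pixel_size = 0.8,
                             wbc_count = 5000L,
                             wbc_nuclear_diameter = c(8, 0.8),
                             clc_nuclear_diameter = c(14, 1.2),
                             small_nuclear_diameter = c(6.8, 0.3),
                             background_level = c(DAPI = 100, CK = 100, CD45 = 100, M4 = 100),
                             noise_sd = 5,
                             shot_noise = TRUE,
                             psf_sigma = 0.8,
                             amplitudes = list(dapi = 500, ck = 400, cd45 = 350, m4 = 300),
                             amplitude_cv = 0.1,
                             ring_width = 2.5,
                             deposition_retention = 0.88,
                             spiking_mode = c("deterministic", "binomial", "poisson"),
                             subtype_mix = c(traditional = 1, small = 0, cluster = 0,
                                             ck_negative = 0, apoptotic = 0),
                             debris_rate = 0,
                             speckle_rate = 0,
                             m4_enabled = FALSE,
                             m4_amplitude = 300,
                             ml_per_slide = 10 / 12,
                             seed = 1L) {
  spiking_mode <- match.arg(spiking_mode)
  tile_shape <- as.integer(tile_shape)
  stopifnot(length(tile_shape) == 2, all(tile_shape >= 64))
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    ctc_error("ctcscope_config_error", "pixel_size must be > 0")
  }
  if (wbc_count < 0) ctc_error("ctcscope_config_error", "wbc_count must be >= 0")
  for (d in list(wbc_nuclear_diameter, clc_nuclear_diameter, small_nuclear_diameter)) {
    if (length(d) != 2 || d[1] <= 0 || d[2] < 0) {
      ctc_error("ctcscope_config_error", "nuclear diameters must be c(mean > 0, sd >= 0)")
    }
  }
  if (deposition_retention < 0 || deposition_retention > 1) {
    ctc_error("ctcscope_config_error", "deposition_retention must be in [0, 1]")
  }
  mix_names <- c("traditional", "small", "cluster", "ck_negative", "apoptotic")
  if (!all(mix_names %in% names(subtype_mix))) {
    ctc_error("ctcscope_config_error",
              paste("subtype_mix must name:", paste(mix_names, collapse = ", ")))
  }
  subtype_mix <- subtype_mix[mix_names]
  if (any(subtype_mix < 0) || abs(sum(subtype_mix) - 1) > 1e-8) {
    ctc_error("ctcscope_config_error", "subtype_mix must be non-negative and sum to 1")
  }
  if (length(noise_sd) == 1) {
    noise_sd <- setNames(rep(noise_sd, 4), c("DAPI", "CK", "CD45", "M4"))
  }
  cfg <- list(
    tile_shape = tile_shape, pixel_size = pixel_size,
    wbc_count = as.integer(wbc_count),
    wbc_nuclear_diameter = wbc_nuclear_diameter,
    clc_nuclear_diameter = clc_nuclear_diameter,
    small_nuclear_diameter = small_nuclear_diameter,
    background_level = background_level, noise_sd = noise_sd,
    shot_noise = isTRUE(shot_noise), psf_sigma = psf_sigma,
    amplitudes = amplitudes, amplitude_cv = amplitude_cv,
    ring_width = ring_width,
    deposition_retention = deposition_retention,
    spiking_mode = spiking_mode, subtype_mix = subtype_mix,
    debris_rate = debris_rate, speckle_rate = speckle_rate,
    m4_enabled = isTRUE(m4_enabled), m4_amplitude = m4_amplitude,
    ml_per_slide = ml_per_slide,
    scale_factor = 3e6 / max(1, wbc_count),
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  cfg
}

#' Segmentation parameters
#'
#' Physical thresholds are expressed in microns and converted through the
#' slide's pixel size, so results are resolution-independent.
#'
#' @param smooth_sigma Gaussian pre-smoothing sigma, microns.
#' @param min_nuclear_area minimum nuclear (group) area, square microns.
#' @param fragment_area_max components at or below this area (square
#'   microns) are candidates for apoptotic fragment grouping.
#' @param grouping_radius fragment grouping radius, microns (about 1.5x a
#'   typical WBC nuclear diameter).
#' @param watershed_tolerance declumping tolerance of the distance-transform
#'   watershed, microns.
#' @param ring_width cytoplasm measurement ring width, microns.
#' @param threshold_k floor on the foreground threshold: background median
#'   plus `threshold_k` background MADs (guards flat/blank rasters).
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(smooth_sigma = 1.0,
                                min_nuclear_area = 12,
                                fragment_area_max = 20,
                                grouping_radius = 12,
                                watershed_tolerance = 1.6,
                                ring_width = 2.0,
                                threshold_k = 5) {
  p <- list(smooth_sigma = smooth_sigma, min_nuclear_area = min_nuclear_area,
            fragment_area_max = fragment_area_max,
            grouping_radius = grouping_radius,
            watershed_tolerance = watershed_tolerance,
            ring_width = ring_width, threshold_k = threshold_k)
  class(p) <- "segmentation_params"
  p
}

#' Classification thresholds
#'
#' @param k marker-positivity gate: a channel is positive when its
#'   background-subtracted per-cell mean exceeds the null-population level
#'   by more than `k` MADs.
#' @param solidity_min minimum nuclear solidity for an intact nucleus.
#' @param condensed_area_frac condensed nucleus: area at or below this
#'   fraction of the median WBC nuclear area ...
#' @param condensed_dapi_factor ... with mean DAPI at or above this multiple
#'   of the median WBC DAPI mean.
#' @param min_wbc minimum number of CD45-positive cells required to build a
#'   slide-internal WBC reference.
#' @return object of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(k = 5,
                                  solidity_min = 0.85,
                                  condensed_area_frac = 0.85,
                                  condensed_dapi_factor = 1.4,
                                  min_wbc = 100) {
  t <- list(k = k, solidity_min = solidity_min,
            condensed_area_frac = condensed_area_frac,
            condensed_dapi_factor = condensed_dapi_factor,
            min_wbc = as.integer(min_wbc))
  class(t) <- "classifier_thresholds"
  t
}

#' Read or write a run configuration file
#'
#' Round-trips the generator / segmentation / classification settings
#' through YAML. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a named list with elements
#'   `generator`, `segmentation`, `classifier`, plus optional `seed` and
#'   `ml_per_slide`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("generator", "segmentation", "classifier", "seed", "ml_per_slide")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    ctc_error("ctcscope_config_error",
              paste("unknown config keys:", paste(extra, collapse = ", ")))
  }
  gen_args <- raw$generator %||% list()
  for (nm in c("subtype_mix", "background_level", "noise_sd")) {
    if (!is.null(gen_args[[nm]])) gen_args[[nm]] <- unlist(gen_args[[nm]])
  }
  if (!is.null(raw$seed)) gen_args$seed <- raw$seed
  list(
    generator = do.call(generator_config, gen_args),
    segmentation = do.call(segmentation_params, raw$segmentation %||% list()),
    classifier = do.call(classifier_thresholds, raw$classifier %||% list()),
    seed = raw$seed %||% (raw$generator$seed %||% 1L),
    ml_per_slide = raw$ml_per_slide %||% (gen_args$ml_per_slide %||% 10 / 12)
  )
}

#' @rdname read_run_config
#' @param config list as returned by `read_run_config()`.
#' @export
write_run_config <- function(config, path) {
  gen <- unclass(config$generator)
  gen$scale_factor <- NULL
  # yaml serializes named atomic vectors as plain sequences; store as maps
  for (nm in c("subtype_mix", "background_level", "noise_sd")) {
    gen[[nm]] <- as.list(gen[[nm]])
  }
  out <- list(generator = gen,
              segmentation = unclass(config$segmentation),
              classifier = unclass(config$classifier),
              seed = config$seed, ml_per_slide = config$ml_per_slide)
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
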