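# Shared test fixtures: small fast configs and a truth <-> detected matcher.

small_config <- function(...) {
  args <- modifyList(list(tile_shape = c(384L, 384L), wbc_count = 200L,
                          seed = 11L), list(...))
  do.call(generator_config, args)
}

mixed_mix <- c(traditional = 0.3, small = 0.2, cluster = 0.2,
               ck_negative = 0.15, apoptotic = 0.15)

small_thresholds <- function(...) {
  do.call(classifier_thresholds, modifyList(list(min_wbc = 50L), list(...)))
}

# nearest-centroid match of truth rows onto detected cells (NA when no cell
# within max_dist microns)
match_truth <- function(truth, cells, pixel_size, max_dist_um = 6) {
  if (!nrow(truth) || !nrow(cells)) return(rep(NA_integer_, nrow(truth)))
  vapply(seq_len(nrow(truth)), function(i) {
    d <- sqrt((cells$x - truth$x[i])^2 + (cells$y - truth$y[i])^2) * pixel_size
    j <- which.min(d)
    if (d[j] <= max_dist_um) j else NA_integer_
  }, integer(1))
}

# full small-slide pipeline returning truth, cells and calls
run_small_pipeline <- function(cfg, n_clc, thresholds = small_thresholds(),
                               slide_index = 1L) {
  s <- generate_slide(cfg, n_clc, slide_index = slide_index)
  res <- enumerate_slide(s$slide, thresholds = thresholds)
  list(truth = s$truth, result = res)
}
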