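test_that("detect_nuclei finds every planted nucleus on a clean slide", {
  cfg <- small_config(seed = 3)
  s <- generate_slide(cfg, 5)
  masks <- detect_nuclei(s$slide)
  expect_s3_class(masks, "nuclei_masks")
  expect_identical(masks$n, nrow(s$truth))
  expect_identical(length(masks$fragment_count), masks$n)
  expect_true(all(sort(unique(as.vector(masks$labels))) == 0:masks$n))
})

test_that("a blank raster yields zero nuclei, not spurious foreground", {
  blank <- structure(list(
    channels = list(DAPI = matrix(100 + rnorm(128^2, 0, 3), 128, 128),
                    CK = matrix(100, 128, 128),
                    CD45 = matrix(100, 128, 128)),
    pixel_size = 0.8, slide_id = "blank", sample_id = "s", operator_id = "o",
    run_id = "r", test_id = "t", metadata = list()), class = "slide_image")
  masks <- detect_nuclei(blank)
  expect_identical(masks$n, 0L)
  cells <- extract_features(blank, masks)
  expect_identical(nrow(cells), 0L)
  res <- enumerate_slide(blank)
  expect_identical(res$dapi_count, 0L)
  expect_true(all(res$counts == 0L))
})

test_that("missing DAPI channel is a typed input error", {
  s <- generate_slide(small_config(), 1)$slide
  s$channels$DAPI <- NULL
  expect_error(detect_nuclei(s), class = "ctcscope_input_error")
})

test_that("watershed declumps touching nuclei", {
  # two discs whose masks touch after blurring must still yield two cells
  m <- matrix(0, 128, 128)
  for (ctr in list(c(60, 64), c(74, 64))) {
    idx <- which(outer((1:128 - ctr[1])^2, (1:128 - ctr[2])^2, "+") <= 6^2)
    m[idx] <- 500
  }
  sl <- structure(list(channels = list(DAPI = m + 100, CK = matrix(100, 128, 128),
                                       CD45 = matrix(100, 128, 128)),
                       pixel_size = 0.8, slide_id = "w", sample_id = "s",
                       operator_id = "o", run_id = "r", test_id = "t",
                       metadata = list()), class = "slide_image")
  expect_identical(detect_nuclei(sl)$n, 2L)
})

test_that("apoptotic fragments group into one cell with fragment_count > 1", {
  cfg <- small_config(subtype_mix = c(traditional = 0, small = 0, cluster = 0,
                                      ck_negative = 0, apoptotic = 1),
                      seed = 7)
  s <- generate_slide(cfg, 4)
  masks <- detect_nuclei(s$slide)
  expect_identical(masks$n, nrow(s$truth))
  cells <- extract_features(s$slide, masks)
  m <- match_truth(s$truth, cells, cfg$pixel_size)
  frag_truth <- s$truth$class == "apoptotic" & s$truth$nuclear_area_px > 0
  ap <- which(s$truth$class == "apoptotic")
  expect_true(all(!is.na(m[ap])))
  # fragmented apoptotics (planned with > 1 fragment) keep their pieces
  planned_frag <- ap[cells$fragment_count[m[ap]] > 1]
  expect_true(all(cells$solidity[m[planned_frag]] < 0.85))
})

test_that("extract_features reports physical units and honest backgrounds", {
  cfg <- small_config(seed = 9)
  s <- generate_slide(cfg, 3)
  masks <- detect_nuclei(s$slide)
  cells <- extract_features(s$slide, masks)
  expect_s3_class(cells, "cell_features")
  expect_identical(nrow(cells), masks$n)
  expect_true(all(cells$nuclear_area_um2 > 0))
  expect_true(all(cells$solidity > 0 & cells$solidity <= 1))
  bg <- attr(cells, "background")
  # configured additive background is 100 per channel
  expect_true(all(abs(unlist(bg) - 100) < 10))
  # WBC DAPI means should sit near the planted amplitude
  m <- match_truth(s$truth, cells, cfg$pixel_size)
  wbc <- which(s$truth$class == "WBC")
  rel <- cells$dapi_mean[m[wbc]] / s$truth$dapi[wbc]
  expect_gt(median(rel), 0.5)  # PSF dilutes but signal dominates
})

test_that("mask / raster shape mismatch is rejected", {
  cfg <- small_config()
  s <- generate_slide(cfg, 1)
  masks <- detect_nuclei(s$slide)
  bad <- s$slide
  bad$channels <- lapply(bad$channels, function(m) m[1:100, 1:100])
  expect_error(extract_features(bad, masks), class = "ctcscope_input_error")
})

test_that("WBC reference summarizes the CD45+ population", {
  cfg <- small_config(seed = 15)
  s <- generate_slide(cfg, 4)
  cells <- extract_features(s$slide, detect_nuclei(s$slide))
  ref <- estimate_wbc_reference(cells, small_thresholds())
  expect_s3_class(ref, "wbc_reference")
  n_wbc_truth <- sum(s$truth$class == "WBC")
  expect_gt(ref$n_wbc, 0.95 * n_wbc_truth)
  expect_lt(ref$n_wbc, 1.05 * n_wbc_truth)
  # median WBC nuclear diameter should be near the configured 8 um
  expect_gt(ref$median_diameter_um, 6.5)
  expect_lt(ref$median_diameter_um, 10.5)
  expect_lt(ref$cd45_threshold, ref$cd45_level)
})

test_that("too few CD45+ cells is a typed reference failure", {
  cfg <- small_config(wbc_count = 20L)
  s <- generate_slide(cfg, 0L)
  cells <- extract_features(s$slide, detect_nuclei(s$slide))
  expect_error(estimate_wbc_reference(cells, classifier_thresholds(min_wbc = 100)),
               class = "ctcscope_reference_failure")
})
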