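test_that("generator_config validates its inputs", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(pixel_size = 0), class = "ctcscope_config_error")
  expect_error(generator_config(wbc_count = -1), class = "ctcscope_config_error")
  expect_error(generator_config(deposition_retention = 1.2),
               class = "ctcscope_config_error")
  expect_error(generator_config(subtype_mix = c(traditional = 0.5, small = 0.2,
                                                cluster = 0.1, ck_negative = 0.1,
                                                apoptotic = 0.05)),
               class = "ctcscope_config_error")
  expect_error(generator_config(clc_nuclear_diameter = c(-1, 1)),
               class = "ctcscope_config_error")
})

test_that("scale factor records the desk-scale stand-in", {
  cfg <- generator_config(wbc_count = 5000)
  expect_equal(cfg$scale_factor, 3e6 / 5000)
})

test_that("identical config and seed give bit-identical slides", {
  cfg <- small_config(seed = 21)
  a <- generate_slide(cfg, 5, slide_index = 3)
  b <- generate_slide(cfg, 5, slide_index = 3)
  expect_identical(a$slide$channels, b$slide$channels)
  expect_identical(a$truth, b$truth)
})

test_that("different slide indices give different slides", {
  cfg <- small_config()
  a <- generate_slide(cfg, 5, slide_index = 1)
  b <- generate_slide(cfg, 5, slide_index = 2)
  expect_false(identical(a$slide$channels$DAPI, b$slide$channels$DAPI))
})

test_that("generation does not disturb the caller's RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_slide(small_config(), 2))
  expect_identical(.Random.seed, before)
})

test_that("deterministic spiking places exactly n_clc CLCs", {
  cfg <- small_config(spiking_mode = "deterministic")
  for (n in c(0L, 4L, 9L)) {
    s <- generate_slide(cfg, n, slide_index = n + 1L)
    expect_identical(sum(s$truth$class != "WBC"), as.integer(n))
  }
})

test_that("stochastic spiking thins by the retention probability", {
  ns <- vapply(1:40, function(i) {
    cfg <- small_config(spiking_mode = "binomial", wbc_count = 10L,
                        deposition_retention = 0.5, seed = i)
    sum(generate_slide(cfg, 20L)$truth$class != "WBC")
  }, numeric(1))
  expect_true(all(ns <= 20))
  expect_gt(mean(ns), 6); expect_lt(mean(ns), 14)
})

test_that("WBC retention is binomial with the configured rate", {
  cfg <- small_config(wbc_count = 300L, deposition_retention = 0.8, seed = 31)
  n_wbc <- vapply(1:10, function(i) {
    sum(generate_slide(cfg, 0L, slide_index = i)$truth$class == "WBC")
  }, numeric(1))
  expect_gt(mean(n_wbc) / 300, 0.75)
  expect_lt(mean(n_wbc) / 300, 0.85)
})

test_that("truth table carries class, cluster and amplitude ground truth", {
  cfg <- small_config(subtype_mix = mixed_mix, seed = 41)
  s <- generate_slide(cfg, 15)
  expect_true(all(s$truth$class %in% c("WBC", "traditional", "small", "cluster",
                                       "ck_negative", "apoptotic")))
  expect_true(all(s$truth$ck[s$truth$class == "ck_negative"] == 0))
  expect_true(all(s$truth$cd45[s$truth$class != "WBC"] == 0))
  cl <- s$truth$cluster_id[s$truth$class == "cluster"]
  if (length(cl)) {
    expect_true(all(!is.na(cl)))
    expect_true(all(table(cl) >= 2))
  }
  expect_true(all(is.na(s$truth$cluster_id[s$truth$class != "cluster"])))
})

test_that("n_clc = 0 marks the slide unspiked; negative n_clc errors", {
  cfg <- small_config()
  s <- generate_slide(cfg, 0L)
  expect_true(s$slide$metadata$unspiked)
  expect_error(generate_slide(cfg, -1), class = "ctcscope_config_error")
})

test_that("infeasible density raises a typed error", {
  cfg <- small_config(tile_shape = c(96L, 96L), wbc_count = 4000L)
  expect_error(generate_slide(cfg, 0L), class = "ctcscope_density_error")
})

test_that("debris objects carry no nucleus and are listed separately", {
  cfg <- small_config(debris_rate = 6, seed = 13)
  s <- generate_slide(cfg, 0L)
  deb <- attr(s$truth, "debris")
  expect_identical(s$slide$metadata$n_debris, nrow(deb))
  expect_false(any(s$truth$class == "debris"))
})

test_that("dilution series manifest has the requested design", {
  cfg <- small_config(wbc_count = 50L)
  ds <- generate_dilution_series(cfg, c(2L, 5L), slides_per_concentration = 4L)
  expect_s3_class(ds, "slide_dataset")
  expect_identical(nrow(ds$manifest), 8L)
  expect_identical(sort(unique(ds$manifest$nominal_clc)), c(2L, 5L))
  expect_true(all(table(ds$manifest$nominal_clc) == 4))
  # two consecutive replicates share a test id
  expect_identical(ds$manifest$test_id[1:4],
                   c("test_1", "test_1", "test_2", "test_2"))
  expect_error(generate_dilution_series(cfg, c(-1L)),
               class = "ctcscope_config_error")
})

test_that("healthy cohort slides are all unspiked", {
  cfg <- small_config(wbc_count = 50L)
  hc <- generate_healthy_cohort(cfg, n_samples = 3L, slides_per_sample = 2L)
  expect_identical(nrow(hc$manifest), 6L)
  expect_true(all(hc$manifest$nominal_clc == 0))
  expect_identical(length(unique(hc$manifest$sample_id)), 3L)
  expect_error(generate_healthy_cohort(cfg, 0L), class = "ctcscope_config_error")
})

test_that("precision study follows the 3-operator / 5-run / 3-test design", {
  cfg <- small_config(wbc_count = 50L)
  ps <- generate_precision_study(cfg, dilutions = 4L)
  m <- ps$manifest
  expect_identical(nrow(m), 30L)  # 5 runs x 3 tests x 2 slides
  expect_identical(sort(unique(m$operator_id)), c("op_1", "op_2", "op_3"))
  expect_identical(length(unique(m$run_id)), 5L)
  runs_per_op <- tapply(m$run_id, m$operator_id, function(r) length(unique(r)))
  expect_equal(runs_per_op[c("op_1", "op_2", "op_3")], c(3L, 1L, 1L),
               ignore_attr = TRUE)
  expect_true(all(table(paste(m$run_id, m$test_id)) == 2))
})
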