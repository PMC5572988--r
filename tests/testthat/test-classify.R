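test_that("call_from_gates implements the rule table exactly", {
  g <- function(ck, cd45, intact, small) {
    data.frame(ck_pos = ck, cd45_pos = cd45, dapi_intact = intact,
               is_small = small)
  }
  expect_identical(call_from_gates(g(TRUE, TRUE, TRUE, FALSE)), "WBC")
  expect_identical(call_from_gates(g(FALSE, TRUE, FALSE, TRUE)), "WBC")
  expect_identical(call_from_gates(g(TRUE, FALSE, FALSE, FALSE)), "APOPTOTIC_CTC")
  expect_identical(call_from_gates(g(TRUE, FALSE, TRUE, FALSE)), "TRADITIONAL_CTC")
  expect_identical(call_from_gates(g(TRUE, FALSE, TRUE, TRUE)), "SMALL_CTC")
  expect_identical(call_from_gates(g(FALSE, FALSE, TRUE, TRUE)), "CK_NEG_CTC")
  expect_identical(call_from_gates(g(FALSE, FALSE, TRUE, FALSE)), "CK_NEG_CTC")
  expect_identical(call_from_gates(g(FALSE, FALSE, FALSE, FALSE)), "UNCLASSIFIED")
})

test_that("classify_cells stores auditable gates consistent with calls", {
  cfg <- small_config(subtype_mix = mixed_mix, seed = 23)
  s <- generate_slide(cfg, 12)
  cells <- extract_features(s$slide, detect_nuclei(s$slide))
  ref <- estimate_wbc_reference(cells, small_thresholds())
  calls <- classify_cells(cells, ref, small_thresholds())
  expect_s3_class(calls, "cell_calls")
  expect_identical(calls$call, call_from_gates(calls))
})

test_that("detect_clusters joins touching CTCs anchored by a traditional", {
  calls <- data.frame(
    cell_id = 1:6,
    call = c("TRADITIONAL_CTC", "SMALL_CTC", "WBC",
             "CK_NEG_CTC", "APOPTOTIC_CTC", "TRADITIONAL_CTC"),
    cluster_id = NA_integer_
  )
  cells <- data.frame(cell_id = 1:6)
  # 1-2 touching (has traditional) | 4-5 touching (no traditional) |
  # 3 is a WBC touching 1 (never joins) | 6 isolated traditional
  cells$neighbour_ids <- list(c(2L, 3L), 1L, 1L, 5L, 4L, integer(0))
  out <- detect_clusters(calls, cells)
  expect_identical(nrow(out$clusters), 1L)
  expect_identical(out$clusters$n_members, 2L)
  expect_identical(sort(out$clusters$member_ids[[1]]), c(1L, 2L))
  expect_identical(out$calls$cluster_id, c(1L, 1L, NA, NA, NA, NA))
  # misaligned inputs are rejected
  expect_error(detect_clusters(calls, cells[c(2:6, 1), ]),
               class = "ctcscope_input_error")
})

test_that("rendered cluster members are detected as one touching cluster", {
  cfg <- small_config(subtype_mix = c(traditional = 0, small = 0, cluster = 1,
                                      ck_negative = 0, apoptotic = 0),
                      seed = 29)
  s <- generate_slide(cfg, 4)
  res <- enumerate_slide(s$slide, thresholds = small_thresholds())
  expect_gte(res$n_clusters, 1L)
  expect_identical(sum(!is.na(res$calls$cluster_id)),
                   sum(s$truth$class == "cluster"))
})

test_that("subtype counts always partition the nucleated-cell count", {
  cfg <- small_config(subtype_mix = mixed_mix, seed = 37)
  for (i in 1:3) {
    res <- enumerate_slide(generate_slide(cfg, 10, slide_index = i)$slide,
                           thresholds = small_thresholds())
    expect_identical(unname(sum(res$counts)), res$dapi_count)
  }
})

test_that("ctc_count selects the requested counting convention", {
  res <- list(counts = c(WBC = 50L, TRADITIONAL_CTC = 4L, SMALL_CTC = 2L,
                         CK_NEG_CTC = 1L, APOPTOTIC_CTC = 3L, UNCLASSIFIED = 0L))
  expect_identical(ctc_count(res, "traditional"), 4L)
  expect_identical(ctc_count(res, "all_candidates"), 10L)
})
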