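test_that("percent_recovery is the plain observed/nominal percentage", {
  expect_equal(percent_recovery(2.64e6, 3e6), 88)
  expect_equal(percent_recovery(c(50, 100), 100), c(50, 100))
  expect_error(percent_recovery(10, 0), class = "ctcscope_input_error")
})

test_that("percent_cv matches the n-1 definition and rejects bad input", {
  v <- c(10, 12, 14, 9, 11)
  expect_equal(percent_cv(v), 100 * sd(v) / mean(v))
  expect_equal(percent_cv(c(5, 5, 5)), 0)
  expect_error(percent_cv(7), class = "ctcscope_cv_error")
  expect_error(percent_cv(c(-1, 1)), class = "ctcscope_cv_error")
  expect_equal(percent_cv(c(10, NA, 12)), 100 * sd(c(10, 12)) / 11)
})

test_that("ctc_per_ml sums a two-slide test over its blood volume", {
  expect_equal(ctc_per_ml(c(3, 5), ml_per_slide = 10 / 12), 8 / (2 * 10 / 12))
  expect_error(ctc_per_ml(c(3, 5, 1), 1), class = "ctcscope_input_error")
  expect_error(ctc_per_ml(c(3, 5), 0), class = "ctcscope_input_error")
})

test_that("fit_linearity recovers a perfect line exactly", {
  nominal <- rep(c(6, 12, 25, 50, 100, 300), each = 6)
  fit <- fit_linearity(nominal, 0.9 * nominal + 2)
  expect_equal(fit$slope, 0.9)
  expect_equal(fit$intercept, 2)
  expect_equal(fit$r_squared, 1)
  expect_identical(fit$n, 36L)
  expect_error(fit_linearity(c(1, 1, 2, 2), c(1, 1, 2, 2)),
               class = "ctcscope_design_error")
})

# brute-force oracle for the four CV definitions
oracle_precision <- function(tests, d) {
  td <- tests[tests$dilution == d, ]
  ref <- "op_1"
  first <- function(op) {
    r <- sort(unique(td$run[td$operator == op]))[1]
    td$value[td$operator == op & td$run == r]
  }
  cv <- function(v) 100 * sd(v) / mean(v)
  c(intra_assay = cv(first(ref)),
    inter_assay = cv(td$value),
    intra_operator = cv(td$value[td$operator == ref]),
    inter_operator = cv(unlist(lapply(unique(td$operator), first))))
}

make_tests <- function(seed = 5) {
  set.seed(seed)
  design <- expand.grid(test = paste0("test_", 1:3),
                        run = paste0("run_", 1:5),
                        dilution = c(25, 300), stringsAsFactors = FALSE)
  design$operator <- ifelse(design$run %in% paste0("run_", 1:3), "op_1",
                            ifelse(design$run == "run_4", "op_2", "op_3"))
  design$value <- design$dilution * exp(rnorm(nrow(design), 0, 0.08))
  design
}

test_that("precision_study matches a brute-force group-by oracle", {
  tests <- make_tests()
  out <- precision_study(tests)
  expect_identical(out$dilution, c(25, 300))
  for (i in 1:2) {
    o <- oracle_precision(tests, out$dilution[i])
    expect_equal(out$intra_assay_cv[i], unname(o["intra_assay"]))
    expect_equal(out$inter_assay_cv[i], unname(o["inter_assay"]))
    expect_equal(out$intra_operator_cv[i], unname(o["intra_operator"]))
    expect_equal(out$inter_operator_cv[i], unname(o["inter_operator"]))
  }
})

test_that("precision_study names every design gap", {
  tests <- make_tests()
  # drop one test from one run
  broken <- tests[-which(tests$run == "run_2" & tests$test == "test_3" &
                           tests$dilution == 25)[1], ]
  err <- tryCatch(precision_study(broken), error = identity)
  expect_s3_class(err, "ctcscope_design_error")
  expect_match(conditionMessage(err), "dilution 25")
  # fewer than 3 operators
  two_ops <- tests[tests$operator != "op_3", ]
  expect_error(precision_study(two_ops), class = "ctcscope_design_error")
  # no operator with 3 runs
  flat <- tests[tests$run %in% paste0("run_", 3:5), ]
  expect_error(precision_study(flat), class = "ctcscope_design_error")
})

test_that("aggregate_tests pairs slides into per-test CTC/mL values", {
  mk <- function(id, op, run, test, dil, n) {
    list(slide_id = id, sample_id = "s", operator_id = op, run_id = run,
         test_id = test,
         counts = c(WBC = 10L, TRADITIONAL_CTC = n, SMALL_CTC = 0L,
                    CK_NEG_CTC = 0L, APOPTOTIC_CTC = 0L, UNCLASSIFIED = 0L))
  }
  results <- list(mk("a", "op_1", "run_1", "test_1", 25, 10L),
                  mk("b", "op_1", "run_1", "test_1", 25, 14L),
                  mk("c", "op_1", "run_1", "test_2", 25, 11L),
                  mk("d", "op_1", "run_1", "test_2", 25, 13L))
  manifest <- data.frame(operator_id = "op_1", run_id = "run_1",
                         test_id = c("test_1", "test_1", "test_2", "test_2"),
                         nominal_clc = 25)
  out <- aggregate_tests(results, manifest, ml_per_slide = 1)
  expect_identical(nrow(out), 2L)
  expect_equal(sort(out$value), c(24 / 2, 24 / 2))
})

test_that("specificity_summary totals CTC calls across unspiked slides", {
  mk <- function(id, n) list(slide_id = id, sample_id = id,
                             counts = c(WBC = 10L, TRADITIONAL_CTC = n,
                                        SMALL_CTC = 0L, CK_NEG_CTC = 0L,
                                        APOPTOTIC_CTC = 0L, UNCLASSIFIED = 0L))
  s <- specificity_summary(list(mk("a", 0L), mk("b", 2L)))
  expect_identical(s$total_ctcs, 2L)
  expect_identical(nrow(s$per_sample), 2L)
})
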