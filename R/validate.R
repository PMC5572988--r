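# Analytical-validation statistics: percent recovery, percent coefficient
# of variation, CLC-per-mL conversion, linearity regression, the four-way
# precision study and specificity summaries.

#' Percent nucleated-cell recovery
#'
#' @param observed_nucleated observed nucleated-cell (DAPI) count.
#' @param nominal_deposited nominal deposited count (> 0).
#' @return percent, `100 * observed / nominal`.
#' @export
#' @examples
#' percent_recovery(2.64e6, 3e6)  # 88
percent_recovery <- function(observed_nucleated, nominal_deposited) {
  if (any(nominal_deposited <= 0)) {
    ctc_error("ctcscope_input_error", "nominal_deposited must be > 0")
  }
  100 * observed_nucleated / nominal_deposited
}

#' Percent coefficient of variation
#'
#' `100 * sd / mean` with the sample (n - 1) standard deviation.
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return percent CV.
#' @export
percent_cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    ctc_error("ctcscope_cv_error", "percent CV requires at least 2 values")
  }
  m <- mean(values)
  if (m == 0) ctc_error("ctcscope_cv_error", "percent CV undefined for zero mean")
  100 * sd(values) / m
}

#' Convert a two-slide test to CTCs per millilitre of blood
#'
#' The enumeration test unit is two replicate slides; their summed count
#' over the blood volume both slides represent gives the reported CTC/mL.
#'
#' @param test_slides either a numeric vector of two per-slide counts, or a
#'   list of two `slide_result`s.
#' @param ml_per_slide millilitres of blood represented per slide (> 0).
#' @param which subtype selector passed to [ctc_count()] when slide results
#'   are supplied.
#' @return CTCs per mL: `sum(counts) / (2 * ml_per_slide)`.
#' @export
ctc_per_ml <- function(test_slides, ml_per_slide,
                       which = c("all_candidates", "traditional")) {
  if (ml_per_slide <= 0) ctc_error("ctcscope_input_error", "ml_per_slide must be > 0")
  counts <- if (is.numeric(test_slides)) test_slides else {
    vapply(test_slides, ctc_count, numeric(1), which = match.arg(which))
  }
  if (length(counts) != 2) {
    ctc_error("ctcscope_input_error", "a test consists of exactly 2 slides")
  }
  sum(counts) / (2 * ml_per_slide)
}

#' Linearity regression of detected versus nominal counts
#'
#' Unweighted ordinary least squares of per-slide detected CLCs on the
#' nominal spike-in concentration; r-squared is the squared Pearson
#' correlation.
#'
#' @param nominal,detected numeric vectors, one entry per slide.
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
fit_linearity <- function(nominal, detected) {
  stopifnot(length(nominal) == length(detected))
  if (length(unique(nominal)) < 3) {
    ctc_error("ctcscope_design_error",
              "linearity requires >= 3 distinct nominal levels")
  }
  fit <- lm(detected ~ nominal)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = unname(cor(nominal, detected)^2), n = length(nominal))
}

#' Four-way precision study
#'
#' Computes intra-assay, inter-assay, intra-operator and inter-operator
#' percent CVs per dilution from test-level CTC/mL values under the
#' standard design: three operators and five runs in total (the reference
#' operator runs on three days, the two others once each), three replicate
#' tests per run.
#'
#' * intra-assay: CV over the 3 tests of the reference operator's first run
#' * inter-assay: CV over all tests of all 5 runs
#' * intra-operator: CV over the reference operator's 9 tests (3 runs)
#' * inter-operator: CV over each operator's first run (9 tests)
#'
#' @param tests data.frame with columns `operator`, `run`, `test`,
#'   `dilution`, `value` (one CTC/mL value per test).
#' @param tests_per_run expected replicate tests per run.
#' @return data.frame, one row per dilution, columns `intra_assay_cv`,
#'   `inter_assay_cv`, `intra_operator_cv`, `inter_operator_cv`.
#' @export
precision_study <- function(tests, tests_per_run = 3L) {
  need <- c("operator", "run", "test", "dilution", "value")
  if (!all(need %in% names(tests))) {
    ctc_error("ctcscope_input_error",
              paste("tests must have columns:", paste(need, collapse = ", ")))
  }
  gaps <- character(0)
  for (d in unique(tests$dilution)) {
    td <- tests[tests$dilution == d, ]
    cnt <- table(paste(td$operator, td$run))
    bad <- names(cnt)[cnt != tests_per_run]
    if (length(bad)) {
      gaps <- c(gaps, sprintf("dilution %s: runs with != %d tests: %s",
                              d, tests_per_run, paste(bad, collapse = "; ")))
    }
    ops <- unique(td$operator)
    if (length(ops) < 3) gaps <- c(gaps, sprintf("dilution %s: < 3 operators", d))
    runs_per_op <- tapply(td$run, td$operator, function(r) length(unique(r)))
    if (!any(runs_per_op >= 3)) {
      gaps <- c(gaps, sprintf("dilution %s: no operator with >= 3 runs", d))
    }
  }
  if (length(gaps)) {
    ctc_error("ctcscope_design_error",
              paste("incomplete precision design:", paste(gaps, collapse = " | ")))
  }
  out <- lapply(sort(unique(tests$dilution)), function(d) {
    td <- tests[tests$dilution == d, ]
    runs_per_op <- tapply(td$run, td$operator, function(r) length(unique(r)))
    ref_op <- names(which(runs_per_op >= 3))[1]
    tdo <- td[td$operator == ref_op, ]
    first_run <- function(x) {
      fr <- tapply(x$run, x$operator, function(r) sort(unique(r))[1])
      x[x$run == fr[x$operator], ]
    }
    data.frame(
      dilution = d,
      intra_assay_cv = percent_cv(tdo$value[tdo$run == sort(unique(tdo$run))[1]]),
      inter_assay_cv = percent_cv(td$value),
      intra_operator_cv = percent_cv(tdo$value),
      inter_operator_cv = percent_cv(first_run(td)$value)
    )
  })
  do.call(rbind, out)
}

#' Aggregate slide results into test-level CTC/mL values
#'
#' Pairs slides of the same (operator, run, test, dilution) and converts
#' each pair with [ctc_per_ml()].
#'
#' @param results list of `slide_result`s.
#' @param manifest data.frame aligned with `results` carrying
#'   `operator_id`, `run_id`, `test_id`, `nominal_clc`.
#' @param ml_per_slide millilitres per slide.
#' @param which subtype selector, see [ctc_per_ml()].
#' @return data.frame with one row per test: `operator`, `run`, `test`,
#'   `dilution`, `value`.
#' @export
aggregate_tests <- function(results, manifest, ml_per_slide,
                            which = "all_candidates") {
  key <- paste(manifest$operator_id, manifest$run_id, manifest$test_id,
               manifest$nominal_clc)
  out <- lapply(split(seq_along(results), key), function(ii) {
    counts <- vapply(results[ii], ctc_count, numeric(1), which = which)
    data.frame(
      operator = manifest$operator_id[ii[1]], run = manifest$run_id[ii[1]],
      test = manifest$test_id[ii[1]], dilution = manifest$nominal_clc[ii[1]],
      value = ctc_per_ml(counts, ml_per_slide), stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Specificity summary over unspiked slides
#'
#' @param results list of `slide_result`s from unspiked slides.
#' @return list with `total_ctcs` (sum of all CTC-subtype calls over all
#'   slides) and `per_sample` (data.frame `sample_id`, `slide_id`,
#'   `ctc_count`).
#' @export
specificity_summary <- function(results) {
  per <- do.call(rbind, lapply(results, function(r) {
    data.frame(sample_id = r$sample_id, slide_id = r$slide_id,
               ctc_count = ctc_count(r, "all_candidates"),
               stringsAsFactors = FALSE)
  }))
  list(total_ctcs = sum(per$ctc_count), per_sample = per)
}
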