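# Study drivers and structured reporting. Two headline per-sample
# aggregations mirror the standard report layout: (a) traditional CTCs
# (cluster members included) and (b) all CTC candidates (traditional +
# small + CK-negative + apoptotic).

# small stable FNV-1a hash for provenance blocks (no external digest dep).
# State is kept as a double; the xor touches only the low byte and the
# 32-bit modular multiply is split into 16-bit halves so every
# intermediate stays below 2^53.
fnv1a <- function(obj) {
  raw <- serialize(obj, NULL, version = 2)
  h <- 2166136261
  p <- 16777619
  for (b in as.integer(raw)) {
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

#' Run CTC enumeration over a set of slides and compile a report
#'
#' Executes segmentation, classification and per-sample CTC/mL conversion
#' for every slide. Slides failing to load or process are flagged in the
#' report; the run fails only if no slide is processable.
#'
#' @param slides either a directory containing `*.tif` slides written by
#'   [write_slide()], a `slide_dataset`, or a list of `slide_image`s.
#' @param params a [segmentation_params()].
#' @param thresholds a [classifier_thresholds()].
#' @param ml_per_slide millilitres of blood represented per slide.
#' @param seed recorded in the provenance block.
#' @return object of class `ctc_report`: list with `samples` (per-sample
#'   data.frame incl. `ctc_per_ml_traditional` and
#'   `ctc_per_ml_all_candidates`), `slide_results`, `failures`,
#'   `provenance`.
#' @export
run_enumeration <- function(slides, params = segmentation_params(),
                            thresholds = classifier_thresholds(),
                            ml_per_slide = 10 / 12, seed = NA_integer_) {
  if (is.character(slides)) {
    paths <- sort(list.files(slides, pattern = "\\.tif$", full.names = TRUE))
    loaded <- lapply(paths, function(p) tryCatch(read_slide(p), error = identity))
  } else if (inherits(slides, "slide_dataset")) {
    loaded <- lapply(slides$slides, `[[`, "slide")
    paths <- vapply(loaded, `[[`, character(1), "slide_id")
  } else {
    loaded <- slides
    paths <- vapply(loaded, `[[`, character(1), "slide_id")
  }
  results <- list(); failures <- list()
  for (i in seq_along(loaded)) {
    res <- if (inherits(loaded[[i]], "error")) loaded[[i]] else {
      tryCatch(enumerate_slide(loaded[[i]], params, thresholds),
               error = identity)
    }
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        slide = as.character(paths[i]), error = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  if (!length(results)) {
    ctc_error("ctcscope_input_error", "no processable slides in the input")
  }
  sample_of <- vapply(results, `[[`, character(1), "sample_id")
  samples <- do.call(rbind, lapply(split(seq_along(results), sample_of),
                                   function(ii) {
    counts <- Reduce(`+`, lapply(results[ii], `[[`, "counts"))
    n <- length(ii)
    data.frame(
      sample_id = results[[ii[1]]]$sample_id, n_slides = n,
      dapi_count = sum(vapply(results[ii], `[[`, numeric(1), "dapi_count")),
      t(counts),
      n_clusters = sum(vapply(results[ii], `[[`, numeric(1), "n_clusters")),
      ctc_per_ml_traditional = unname(counts["TRADITIONAL_CTC"]) / (n * ml_per_slide),
      ctc_per_ml_all_candidates = sum(counts[CTC_CLASSES]) / (n * ml_per_slide),
      stringsAsFactors = FALSE
    )
  }))
  rownames(samples) <- NULL
  structure(list(
    samples = samples, slide_results = results,
    failures = if (length(failures)) do.call(rbind, failures) else NULL,
    provenance = list(
      package_version = as.character(utils::packageVersion("ctcscope")),
      seed = seed, ml_per_slide = ml_per_slide,
      config_hash = fnv1a(list(params, thresholds, ml_per_slide)),
      schema = "ctcscope-report/1"
    )
  ), class = "ctc_report")
}

#' Write a report as JSON plus flat CSV mirrors
#'
#' @param report a `ctc_report` or `validation_summary`.
#' @param dir output directory.
#' @param timestamp include a timestamp in the JSON (off by default so
#'   identical runs are byte-identical).
#' @return path of the JSON file, invisibly.
#' @export
write_report <- function(report, dir, timestamp = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- unclass(report)
  out$slide_results <- lapply(out$slide_results, function(r) {
    list(slide_id = r$slide_id, sample_id = r$sample_id,
         operator_id = r$operator_id, run_id = r$run_id, test_id = r$test_id,
         dapi_count = r$dapi_count, counts = as.list(r$counts),
         n_clusters = r$n_clusters)
  })
  if (timestamp) out$provenance$timestamp <- format(Sys.time(), tz = "UTC")
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(out, jp, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(report$samples)) {
    write.csv(report$samples, file.path(dir, "samples.csv"), row.names = FALSE)
  }
  invisible(jp)
}

#' Run the full analytical-validation study
#'
#' Generates (or ingests) the dilution-series and unspiked-slide datasets,
#' enumerates every slide, and compiles recovery, linearity and
#' specificity statistics; optionally adds the four-way precision study.
#'
#' @param config a [generator_config()].
#' @param concentrations nominal CLCs/slide of the dilution series.
#' @param slides_per_concentration replicate slides per concentration.
#' @param n_unspiked unspiked healthy-donor slides.
#' @param params,thresholds pipeline settings.
#' @param include_precision also run the precision design (adds 60 slides
#'   at the standard two dilutions).
#' @return object of class `validation_summary`: `recovery` (per-dilution
#'   mean percent recovery and CV), `mean_percent_recovery`, `linearity`
#'   (slope/intercept/r_squared), `specificity`, optional `precision`, and
#'   the per-slide `detail` table.
#' @export
run_validation_study <- function(config,
                                 concentrations = c(6L, 12L, 25L, 50L, 100L, 300L),
                                 slides_per_concentration = 6L,
                                 n_unspiked = 5L,
                                 params = segmentation_params(),
                                 thresholds = classifier_thresholds(),
                                 include_precision = FALSE) {
  dil <- generate_dilution_series(config, concentrations,
                                  slides_per_concentration)
  unsp_cfg <- config
  unsp <- generate_healthy_cohort(unsp_cfg, n_samples = n_unspiked,
                                  slides_per_sample = 1L)
  run1 <- function(entry) enumerate_slide(entry$slide, params, thresholds)
  dil_res <- lapply(dil$slides, run1)
  unsp_res <- lapply(unsp$slides, run1)

  detail <- data.frame(
    dil$manifest,
    dapi_count = vapply(dil_res, `[[`, numeric(1), "dapi_count"),
    detected_clc = vapply(dil_res, ctc_count, numeric(1), "all_candidates")
  )
  unsp_detail <- data.frame(
    unsp$manifest,
    dapi_count = vapply(unsp_res, `[[`, numeric(1), "dapi_count"),
    detected_clc = vapply(unsp_res, ctc_count, numeric(1), "all_candidates")
  )
  all_detail <- rbind(detail, unsp_detail)
  all_detail$recovery <- percent_recovery(all_detail$dapi_count,
                                          all_detail$nominal_cells)
  recovery <- do.call(rbind, lapply(split(all_detail, all_detail$nominal_clc),
                                    function(d) data.frame(
    nominal_clc = d$nominal_clc[1],
    mean_recovery = mean(d$recovery),
    cv_recovery = if (nrow(d) > 1) percent_cv(d$recovery) else NA_real_
  )))
  rownames(recovery) <- NULL

  lin <- fit_linearity(detail$nominal_clc, detail$detected_clc)
  spec <- specificity_summary(unsp_res)

  precision <- NULL
  if (include_precision) {
    prec <- generate_precision_study(config)
    prec_res <- lapply(prec$slides, run1)
    tests <- aggregate_tests(prec_res, prec$manifest, config$ml_per_slide)
    precision <- precision_study(tests)
  }
  structure(list(
    recovery = recovery,
    mean_percent_recovery = mean(all_detail$recovery),
    linearity = lin,
    specificity = spec,
    precision = precision,
    detail = all_detail,
    provenance = list(
      package_version = as.character(utils::packageVersion("ctcscope")),
      seed = config$seed, scale_factor = config$scale_factor,
      schema = "ctcscope-validation/1"
    )
  ), class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat("Analytical validation summary\n")
  cat(sprintf("  mean percent recovery: %.1f %%\n", x$mean_percent_recovery))
  cat(sprintf("  linearity: slope %.3f, intercept %.3f, r^2 %.4f (n=%d slides)\n",
              x$linearity$slope, x$linearity$intercept, x$linearity$r_squared,
              x$linearity$n))
  cat(sprintf("  specificity: %d CTCs on %d unspiked slides\n",
              x$specificity$total_ctcs, nrow(x$specificity$per_sample)))
  if (!is.null(x$precision)) { cat("  precision (%CV):\n"); print(x$precision) }
  invisible(x)
}
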