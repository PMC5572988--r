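# Rule-based CTC subtype classification. Gate definitions:
#   ck_pos / cd45_pos : background-subtracted marker mean above the
#     slide-internal null level by more than k MADs (CK null = the WBC
#     population; CD45 null = the provisionally CD45-negative population).
#   dapi_intact : single nuclear fragment, solidity >= solidity_min, and
#     not condensed (condensed = area <= condensed_area_frac x median WBC
#     nuclear area with DAPI mean >= condensed_dapi_factor x WBC median).
#   is_small : nuclear equivalent diameter at or below the median WBC
#     diameter of the same slide.
# Decision order: CD45+ -> WBC; CK+ & !intact -> apoptotic; CK+ & intact ->
# traditional or small by size; CK- & CD45- & intact -> CK-negative CTC;
# anything else -> unclassified.

compute_gates <- function(cells, ref, thresholds) {
  ck_thr <- ref$ck_level + thresholds$k * ref$ck_mad
  condensed <- cells$nuclear_area_um2 <= thresholds$condensed_area_frac * ref$median_area_um2 &
    cells$dapi_mean >= thresholds$condensed_dapi_factor * ref$median_dapi
  intact <- cells$fragment_count == 1L &
    cells$solidity >= thresholds$solidity_min & !condensed
  data.frame(
    cell_id = cells$cell_id,
    ck_pos = cells$ck_mean > ck_thr,
    cd45_pos = cells$cd45_mean > ref$cd45_threshold,
    dapi_intact = intact,
    is_small = cells$equivalent_diameter_um <= ref$median_diameter_um,
    is_apoptotic = cells$ck_mean > ck_thr & !intact
  )
}

#' Re-derive calls from stored boolean gates
#'
#' The rule table is a pure function of the five gates, making every call
#' auditable from the gate record alone.
#'
#' @param gates data.frame with logical columns `ck_pos`, `cd45_pos`,
#'   `dapi_intact`, `is_small`.
#' @return character vector of calls.
#' @export
call_from_gates <- function(gates) {
  ifelse(gates$cd45_pos, "WBC",
  ifelse(gates$ck_pos & !gates$dapi_intact, "APOPTOTIC_CTC",
  ifelse(gates$ck_pos & gates$dapi_intact & !gates$is_small, "TRADITIONAL_CTC",
  ifelse(gates$ck_pos & gates$dapi_intact & gates$is_small, "SMALL_CTC",
  ifelse(!gates$ck_pos & !gates$cd45_pos & gates$dapi_intact, "CK_NEG_CTC",
         "UNCLASSIFIED")))))
}

#' Classify every cell into WBC or a CTC subtype
#'
#' @param cells a `cell_features` data.frame.
#' @param ref a `wbc_reference` from [estimate_wbc_reference()].
#' @param thresholds a [classifier_thresholds()].
#' @return data.frame of class `cell_calls`: `cell_id`, `call`, the five
#'   boolean gates, and `cluster_id` (NA until [detect_clusters()] runs).
#' @export
classify_cells <- function(cells, ref, thresholds = classifier_thresholds()) {
  stopifnot(inherits(ref, "wbc_reference"))
  gates <- compute_gates(cells, ref, thresholds)
  calls <- data.frame(
    cell_id = gates$cell_id,
    call = call_from_gates(gates),
    gates[-1],
    cluster_id = NA_integer_
  )
  class(calls) <- c("cell_calls", "data.frame")
  calls
}

#' Detect CTC clusters
#'
#' Connected components over the touching-cytoplasm graph restricted to
#' CTC-called cells; components with two or more members, at least one of
#' them a traditional CTC, are reported and their members receive a
#' `cluster_id`.
#'
#' @param calls a `cell_calls` data.frame.
#' @param cells the matching `cell_features` (source of `neighbour_ids`).
#' @return list with `clusters` (data.frame: `cluster_id`, `n_members`,
#'   `contains_traditional`, list column `member_ids`) and `calls` (the
#'   input with `cluster_id` filled in).
#' @export
detect_clusters <- function(calls, cells) {
  if (!identical(calls$cell_id, cells$cell_id)) {
    ctc_error("ctcscope_input_error", "calls and cells are not aligned by cell_id")
  }
  is_ctc <- calls$call %in% CTC_CLASSES
  n <- nrow(calls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in which(is_ctc)) {
    for (j in cells$neighbour_ids[[i]]) {
      if (j > i && is_ctc[j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  root[!is_ctc] <- NA_integer_
  comp <- split(which(is_ctc), root[is_ctc])
  clusters <- list(); cid <- 0L
  calls$cluster_id <- NA_integer_
  for (members in comp) {
    if (length(members) < 2) next
    if (!any(calls$call[members] == "TRADITIONAL_CTC")) next
    cid <- cid + 1L
    calls$cluster_id[members] <- cid
    clusters[[cid]] <- data.frame(cluster_id = cid, n_members = length(members),
                                  contains_traditional = TRUE)
    clusters[[cid]]$member_ids <- list(members)
  }
  clusters <- if (cid) do.call(rbind, clusters) else
    data.frame(cluster_id = integer(0), n_members = integer(0),
               contains_traditional = logical(0))
  list(clusters = clusters, calls = calls)
}

#' Segment, classify and enumerate one slide
#'
#' Runs the full per-slide pipeline: nucleus detection, feature extraction,
#' WBC reference estimation, subtype classification and cluster detection,
#' then compiles counts. `dapi_count` is the total number of nucleated
#' cells; subtype counts plus WBC plus UNCLASSIFIED always partition it.
#' Cluster members are included in their subtype counts and the cluster
#' count is reported alongside, so either counting convention can be
#' derived.
#'
#' @param slide a `slide_image`.
#' @param params a [segmentation_params()].
#' @param thresholds a [classifier_thresholds()].
#' @return object of class `slide_result`: identifiers, `dapi_count`,
#'   named `counts` over all call classes, `n_clusters`, plus the full
#'   `cells`, `calls`, `clusters` tables and the `wbc_reference` (NULL for
#'   an empty slide).
#' @export
enumerate_slide <- function(slide, params = segmentation_params(),
                            thresholds = classifier_thresholds()) {
  masks <- detect_nuclei(slide, params)
  ids <- slide[c("slide_id", "sample_id", "operator_id", "run_id", "test_id")]
  if (masks$n == 0L) {
    return(structure(c(ids, list(
      dapi_count = 0L, counts = setNames(integer(length(ALL_CALLS)), ALL_CALLS),
      n_clusters = 0L, cells = NULL, calls = NULL, clusters = NULL,
      wbc_reference = NULL, metadata = slide$metadata
    )), class = "slide_result"))
  }
  cells <- extract_features(slide, masks, params)
  ref <- estimate_wbc_reference(cells, thresholds)
  calls <- classify_cells(cells, ref, thresholds)
  cl <- detect_clusters(calls, cells)
  counts <- setNames(integer(length(ALL_CALLS)), ALL_CALLS)
  tab <- table(cl$calls$call)
  counts[names(tab)] <- as.integer(tab)
  structure(c(ids, list(
    dapi_count = nrow(cells), counts = counts,
    n_clusters = nrow(cl$clusters), cells = cells, calls = cl$calls,
    clusters = cl$clusters, wbc_reference = ref, metadata = slide$metadata
  )), class = "slide_result")
}

#' @export
print.slide_result <- function(x, ...) {
  cat(sprintf("<slide_result %s> %d nucleated cells\n", x$slide_id, x$dapi_count))
  print(x$counts)
  if (x$n_clusters) cat(sprintf("clusters: %d\n", x$n_clusters))
  invisible(x)
}

#' Total CTC count of a slide result
#'
#' @param result a `slide_result`.
#' @param which `"all_candidates"` (all four subtypes) or `"traditional"`
#'   (traditional CTCs only, cluster members included).
#' @return integer count.
#' @export
ctc_count <- function(result, which = c("all_candidates", "traditional")) {
  which <- match.arg(which)
  if (which == "traditional") {
    unname(result$counts["TRADITIONAL_CTC"])
  } else {
    sum(result$counts[CTC_CLASSES])
  }
}
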