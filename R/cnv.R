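# Windowed copy-number profiles: depth-normalized log2 ratio of per-window
# read counts of a single cell versus a matched control, in fixed 100-kb
# genomic windows (0-based half-open).

#' Tile a genome into fixed windows
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param window_size window width, bp (default 100 kb). The trailing
#'   partial window of each chromosome is kept.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), sorted
#'   and non-overlapping.
#' @export
make_genome_windows <- function(chrom_lengths, window_size = 1e5) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  out <- lapply(names(chrom_lengths), function(ch) {
    starts <- seq(0, chrom_lengths[[ch]] - 1, by = window_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, chrom_lengths[[ch]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate per-window read counts
#'
#' Poisson counts with a per-window copy-number multiplier, with optional
#' uniform window dropout; the oracle-side generator for the CNV module.
#'
#' @param windows data.frame from [make_genome_windows()].
#' @param multiplier scalar or per-window relative copy multiplier.
#' @param mean_depth expected reads per unit-multiplier window.
#' @param dropout_rate probability a window reports zero reads regardless
#'   of copy number.
#' @param seed integer seed.
#' @return integer vector of counts aligned with `windows`.
#' @export
simulate_cnv_counts <- function(windows, multiplier = 1, mean_depth = 100,
                                dropout_rate = 0, seed = 1L) {
  m <- rep_len(multiplier, nrow(windows))
  with_seed(seed, {
    counts <- rpois(nrow(windows), mean_depth * m)
    if (dropout_rate > 0) {
      counts[runif(nrow(windows)) < dropout_rate] <- 0L
    }
    counts
  })
}

#' Windowed log2 copy-number profile versus a control
#'
#' Depth-normalizes both count vectors by their totals (library size) and
#' reports `log2((sample/total_s) / (control/total_c))` per window. Windows
#' with zero control counts are flagged missing (NA).
#'
#' @param sample_counts,control_counts per-window read counts aligned with
#'   `windows`.
#' @param windows data.frame `chrom`, `start`, `end`.
#' @param sample_id,control_id identifiers stored on the profile.
#' @return data.frame of class `cnv_profile`: windows plus `log2_ratio`.
#' @export
cnv_profile <- function(sample_counts, control_counts, windows,
                        sample_id = "sample", control_id = "control") {
  if (length(sample_counts) != nrow(windows) ||
      length(control_counts) != nrow(windows)) {
    ctc_error("ctcscope_input_error", "counts do not match the window list")
  }
  if (sum(sample_counts) <= 0 || sum(control_counts) <= 0) {
    ctc_error("ctcscope_input_error", "total read counts must be > 0")
  }
  o <- order(windows$chrom, windows$start)
  if (!identical(o, seq_len(nrow(windows)))) {
    windows <- windows[o, ]
    sample_counts <- sample_counts[o]; control_counts <- control_counts[o]
  }
  s <- sample_counts / sum(sample_counts)
  c0 <- control_counts / sum(control_counts)
  lr <- ifelse(control_counts > 0 & sample_counts > 0, log2(s / c0), NA_real_)
  lr[control_counts > 0 & sample_counts == 0] <- -Inf
  lr[control_counts == 0] <- NA_real_
  prof <- windows
  prof$log2_ratio <- lr
  attr(prof, "sample_id") <- sample_id
  attr(prof, "control_id") <- control_id
  class(prof) <- c("cnv_profile", "data.frame")
  prof
}

#' Call focal gene amplification from a CNV profile
#'
#' @param profile a `cnv_profile`.
#' @param gene_window list or data.frame with `chrom`, `start`, `end`
#'   (0-based half-open) locating the gene.
#' @param threshold minimum mean log2 ratio over the overlapping windows to
#'   call amplification (default +1, one extra copy doubling).
#' @return list with `amplified` (logical), `score` (mean log2 ratio over
#'   overlapping finite windows) and `n_windows`.
#' @export
call_gene_amplification <- function(profile, gene_window, threshold = 1.0) {
  ov <- profile$chrom == gene_window$chrom &
    profile$start < gene_window$end & profile$end > gene_window$start
  if (!any(ov)) {
    ctc_error("ctcscope_input_error", "gene window overlaps no profile window")
  }
  vals <- profile$log2_ratio[ov]
  vals <- vals[is.finite(vals)]
  score <- if (length(vals)) mean(vals) else NA_real_
  list(amplified = isTRUE(score >= threshold), score = score,
       n_windows = sum(ov))
}

#' Read or write BED-like per-window tables
#'
#' Tab-separated `chrom`, `start`, `end`, plus `count` (input tables) or
#' `log2_ratio` (profiles). No headers, 0-based half-open coordinates.
#'
#' @param path TSV file path.
#' @return `read_window_counts()`: data.frame `chrom,start,end,count`.
#' @export
read_window_counts <- function(path) {
  df <- read.delim(path, header = FALSE,
                   col.names = c("chrom", "start", "end", "count"),
                   stringsAsFactors = FALSE)
  df
}

#' @rdname read_window_counts
#' @param windows window data.frame.
#' @param counts per-window counts.
#' @export
write_window_counts <- function(windows, counts, path) {
  write.table(cbind(windows[c("chrom", "start", "end")], count = counts),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname read_window_counts
#' @param profile a `cnv_profile` to write.
#' @export
write_cnv_profile <- function(profile, path) {
  write.table(profile[c("chrom", "start", "end", "log2_ratio")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Plot a CNV profile along one chromosome
#'
#' Scatter of per-window log2 ratios against genomic position, with an
#' optional highlighted gene window.
#'
#' @param profile a `cnv_profile`.
#' @param chrom chromosome to plot (default: first in the profile).
#' @param gene_window optional list `chrom`, `start`, `end` to highlight.
#' @param ... passed to [graphics::plot()].
#' @export
plot_cnv_profile <- function(profile, chrom = profile$chrom[1],
                             gene_window = NULL, ...) {
  p <- profile[profile$chrom == chrom, ]
  x <- (p$start + p$end) / 2
  graphics::plot(x, p$log2_ratio, pch = 16, cex = 0.4,
                 xlab = sprintf("%s position (bp)", chrom),
                 ylab = "log2 copy-number ratio", ...)
  graphics::abline(h = 0, col = "grey60")
  if (!is.null(gene_window) && identical(gene_window$chrom, chrom)) {
    graphics::abline(v = c(gene_window$start, gene_window$end),
                     lty = 3, col = "goldenrod")
  }
  invisible(profile)
}
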