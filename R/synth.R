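# Synthetic slide generator: renders desk-scale immunofluorescent tiles
# (DAPI / CK / CD45 / optional M4) with per-cell ground truth. Appearance
# model: nuclei as truncated ellipses, cytoplasmic markers as discs, one
# Gaussian PSF convolution per channel, then Poisson shot noise plus
# Gaussian read noise.

# Retained spike count for a nominal n_clc. Deterministic mode represents a
# verified spike count and places exactly n_clc cells; the stochastic modes
# thin by the deposition retention probability.
draw_spiked_count <- function(n_clc, mode, retention) {
  switch(mode,
    deterministic = as.integer(n_clc),
    binomial = rbinom(1L, as.integer(n_clc), retention),
    poisson = rpois(1L, n_clc * retention)
  )
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

# ---- cell plan ------------------------------------------------------------

# Decide classes, sizes and amplitudes for every object on the tile.
plan_cells <- function(config, n_clc) {
  amp <- function(mean_amp, n = 1) {
    mean_amp * pmax(0.3, rnorm(n, 1, config$amplitude_cv))
  }
  wbc_n <- rbinom(1L, config$wbc_count, config$deposition_retention)
  clc_n <- draw_spiked_count(n_clc, config$spiking_mode, config$deposition_retention)

  rows <- list()
  add <- function(class, r_um, kind, cluster_id = NA_integer_, condensed = FALSE,
                  n_frag = 1L, a_dapi = 0, a_ck = 0, a_cd45 = 0, a_m4 = 0) {
    rows[[length(rows) + 1L]] <<- data.frame(
      class = class, kind = kind, r_um = r_um, cluster_id = cluster_id,
      condensed = condensed, n_frag = as.integer(n_frag),
      amp_dapi = a_dapi, amp_ck = a_ck, amp_cd45 = a_cd45, amp_m4 = a_m4,
      stringsAsFactors = FALSE
    )
  }

  a <- config$amplitudes
  m4a <- if (config$m4_enabled) config$m4_amplitude else 0
  clc_r <- function() rtrunc_norm(1, config$clc_nuclear_diameter[1] / 2,
                                  config$clc_nuclear_diameter[2] / 2, 5.5, 8.5)
  if (clc_n > 0) {
    classes <- sample(names(config$subtype_mix), clc_n, replace = TRUE,
                      prob = config$subtype_mix)
    next_cluster <- 1L
    i <- 1L
    while (i <= clc_n) {
      cls <- classes[i]
      if (cls == "cluster") {
        # a cluster consumes 2-5 of the remaining CLC budget
        k <- min(sample(2:5, 1L), clc_n - i + 1L)
        if (k < 2L) cls <- "traditional" else {
          for (j in seq_len(k)) {
            add("cluster", clc_r(), "clc", cluster_id = next_cluster,
                a_dapi = amp(a$dapi), a_ck = amp(a$ck),
                a_m4 = if (m4a > 0) amp(m4a) else 0)
          }
          next_cluster <- next_cluster + 1L
          i <- i + k
          next
        }
      }
      if (cls == "traditional") {
        add("traditional", clc_r(), "clc", a_dapi = amp(a$dapi),
            a_ck = amp(a$ck), a_m4 = if (m4a > 0) amp(m4a) else 0)
      } else if (cls == "small") {
        add("small", rtrunc_norm(1, config$small_nuclear_diameter[1] / 2,
                                 config$small_nuclear_diameter[2] / 2, 2.75, 3.7),
            "clc", a_dapi = amp(a$dapi), a_ck = amp(a$ck),
            a_m4 = if (m4a > 0) amp(m4a) else 0)
      } else if (cls == "ck_negative") {
        add("ck_negative", clc_r(), "clc", a_dapi = amp(a$dapi),
            a_m4 = if (m4a > 0) amp(m4a) else 0)
      } else if (cls == "apoptotic") {
        condensed <- runif(1) < 0.5
        add("apoptotic", clc_r(), "clc", condensed = condensed,
            n_frag = if (condensed) 1L else sample(2:5, 1L),
            a_dapi = amp(a$dapi) * if (condensed) 3.2 else 1,
            a_ck = amp(a$ck), a_m4 = if (m4a > 0) amp(m4a) else 0)
      }
      i <- i + 1L
    }
  }
  if (wbc_n > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      class = "WBC", kind = "wbc",
      r_um = rtrunc_norm(wbc_n, config$wbc_nuclear_diameter[1] / 2,
                         config$wbc_nuclear_diameter[2] / 2, 2.75, 5.25),
      cluster_id = NA_integer_, condensed = FALSE, n_frag = 1L,
      amp_dapi = amp(a$dapi, wbc_n), amp_ck = 0,
      amp_cd45 = amp(a$cd45, wbc_n), amp_m4 = 0, stringsAsFactors = FALSE
    )
  }
  n_debris <- if (config$debris_rate > 0) rpois(1L, config$debris_rate) else 0L
  if (n_debris > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      class = "debris", kind = "debris", r_um = runif(n_debris, 2.5, 5),
      cluster_id = NA_integer_, condensed = FALSE, n_frag = 1L,
      amp_dapi = 0, amp_ck = amp(a$ck, n_debris), amp_cd45 = 0, amp_m4 = 0,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(class = character(), kind = character(), r_um = numeric(),
                      cluster_id = integer(), condensed = logical(),
                      n_frag = integer(), amp_dapi = numeric(), amp_ck = numeric(),
                      amp_cd45 = numeric(), amp_m4 = numeric()))
  }
  do.call(rbind, rows)
}

# ---- placement ------------------------------------------------------------

# Random sequential placement with pairwise clearance enforced through a
# spatial hash grid. CLCs get full cytoplasm clearance from every other
# object so marker halos never overlap across cells; WBC halos may touch
# (harmless: cluster calls only consider CTC-classified cells).
place_cells <- function(plan, config) {
  h <- config$tile_shape[1]; w <- config$tile_shape[2]
  px <- config$pixel_size
  ring <- config$ring_width / px
  r_px <- plan$r_um / px
  kind <- plan$kind

  # feasibility bound: effective footprints must not exceed 55 % of the tile
  r_eff <- r_px + ifelse(kind == "clc", ring + 4 / px, 0.75 / px)
  if (sum(pi * r_eff^2) > 0.55 * h * w) {
    ctc_error("ctcscope_density_error",
              sprintf("requested %d objects exceed the packing-feasibility bound for a %dx%d tile",
                      nrow(plan), h, w))
  }

  # cluster members are placed as rigid chains around a cluster centre
  offsets_x <- numeric(nrow(plan)); offsets_y <- numeric(nrow(plan))
  unit_of <- seq_len(nrow(plan))     # placement unit id per row
  unit_r <- r_px                      # bounding radius of each unit
  gap_cluster <- 3 / px
  for (cid in unique(plan$cluster_id[!is.na(plan$cluster_id)])) {
    idx <- which(plan$cluster_id == cid)
    ox <- 0; oy <- 0; ang <- runif(1, 0, 2 * pi)
    for (j in seq_along(idx)) {
      if (j > 1) {
        s <- r_px[idx[j - 1]] + r_px[idx[j]] + gap_cluster
        ang <- ang + runif(1, -pi / 3, pi / 3)
        ox <- ox + s * cos(ang); oy <- oy + s * sin(ang)
      }
      offsets_x[idx[j]] <- ox; offsets_y[idx[j]] <- oy
    }
    cx <- mean(offsets_x[idx]); cy <- mean(offsets_y[idx])
    offsets_x[idx] <- offsets_x[idx] - cx; offsets_y[idx] <- offsets_y[idx] - cy
    unit_of[idx] <- idx[1]
    unit_r[idx[1]] <- max(sqrt(offsets_x[idx]^2 + offsets_y[idx]^2) + r_px[idx])
  }
  units <- unique(unit_of)
  # place big clearance-hungry units first
  units <- units[order(match(kind[units], c("clc", "debris", "wbc")),
                       -unit_r[units])]

  min_gap <- function(ki, kj) {
    if (ki == "clc" || kj == "clc") return(2 * ring + 4 / px)
    if (ki == "debris" || kj == "debris") return(ring + 2 / px)
    1.5 / px
  }
  cell_sz <- max(2 * (unit_r + ring)) + 4 / px
  ngx <- max(1L, ceiling(w / cell_sz)); ngy <- max(1L, ceiling(h / cell_sz))
  grid <- vector("list", ngx * ngy)
  np <- length(units)
  placed_x <- numeric(np); placed_y <- numeric(np); placed_u <- integer(np)
  n_placed <- 0L

  ux <- numeric(length(unit_of)); uy <- numeric(length(unit_of))
  for (u in units) {
    margin <- unit_r[u] + ring + 2
    ok <- FALSE
    for (try in seq_len(400L)) {
      x <- runif(1, margin, w - margin); y <- runif(1, margin, h - margin)
      gx <- pmin(pmax(floor(x / cell_sz) + 1, 1), ngx)
      gy <- pmin(pmax(floor(y / cell_sz) + 1, 1), ngy)
      neigh <- integer(0)
      for (dx in -1:1) for (dy in -1:1) {
        gxx <- gx + dx; gyy <- gy + dy
        if (gxx >= 1 && gxx <= ngx && gyy >= 1 && gyy <= ngy) {
          neigh <- c(neigh, grid[[(gyy - 1L) * ngx + gxx]])
        }
      }
      if (length(neigh)) {
        d <- sqrt((placed_x[neigh] - x)^2 + (placed_y[neigh] - y)^2)
        req <- vapply(neigh, function(v) {
          unit_r[u] + unit_r[placed_u[v]] + min_gap(kind[placed_u[v]], kind[u])
        }, numeric(1))
        if (any(d < req)) next
      }
      ok <- TRUE
      n_placed <- n_placed + 1L
      placed_x[n_placed] <- x; placed_y[n_placed] <- y; placed_u[n_placed] <- u
      grid[[(gy - 1L) * ngx + gx]] <- c(grid[[(gy - 1L) * ngx + gx]], n_placed)
      ux[u] <- x; uy[u] <- y
      break
    }
    if (!ok) {
      ctc_error("ctcscope_density_error",
                "could not place all objects: tile density too high")
    }
  }
  plan$x <- ux[unit_of] + offsets_x
  plan$y <- uy[unit_of] + offsets_y
  plan
}

# ---- rendering ------------------------------------------------------------

# linear indices of the pixels inside an ellipse (0-based centre coords).
# Returning indices instead of a modified matrix keeps rendering O(total
# painted area): passing the full channel matrix through a function
# boundary triggers a copy per call under R's copy-on-modify.
ellipse_idx <- function(h, w, cx, cy, a, b, phi) {
  rmax <- max(a, b)
  x0 <- max(1L, floor(cx + 1 - rmax - 1)); x1 <- min(w, ceiling(cx + 1 + rmax + 1))
  y0 <- max(1L, floor(cy + 1 - rmax - 1)); y1 <- min(h, ceiling(cy + 1 + rmax + 1))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  dx <- matrix(xs - 1 - cx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  dy <- matrix(ys - 1 - cy, nrow = length(ys), ncol = length(xs))
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  col <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  row <- matrix(ys, nrow = length(ys), ncol = length(xs))
  (col[inside] - 1L) * h + row[inside]
}

gaussian_kernel <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  g <- dnorm(-r:r, sd = sigma_px)
  g <- g / sum(g)
  outer(g, g)
}

render_slide <- function(plan, config) {
  h <- config$tile_shape[1]; w <- config$tile_shape[2]
  px <- config$pixel_size
  chan_names <- c("DAPI", "CK", "CD45", if (config$m4_enabled) "M4")
  # accumulate into local matrices via linear indices (no cross-function
  # matrix passing: see ellipse_idx)
  m_dapi <- matrix(0, h, w); m_ck <- matrix(0, h, w)
  m_cd45 <- matrix(0, h, w)
  m_m4 <- if (config$m4_enabled) matrix(0, h, w) else NULL

  n <- nrow(plan)
  n_cells <- if (n > 0) sum(plan$class != "debris") else 0L
  truth <- data.frame(
    cell_id = seq_len(n_cells), x = numeric(n_cells), y = numeric(n_cells),
    class = character(n_cells), cluster_id = rep(NA_integer_, n_cells),
    nuclear_area_px = integer(n_cells), dapi = numeric(n_cells),
    ck = numeric(n_cells), cd45 = numeric(n_cells), m4 = numeric(n_cells),
    stringsAsFactors = FALSE
  )
  debris_x <- numeric(0); debris_y <- numeric(0)
  cell_id <- 0L
  for (i in seq_len(n)) {
    cls <- plan$class[i]
    cx <- plan$x[i]; cy <- plan$y[i]
    r <- plan$r_um[i] / px
    if (cls == "debris") {
      idx <- ellipse_idx(h, w, cx, cy, r, r, 0)
      m_ck[idx] <- m_ck[idx] + plan$amp_ck[i]
      debris_x <- c(debris_x, cx); debris_y <- c(debris_y, cy)
      next
    }
    cell_id <- cell_id + 1L
    r_cyto <- r + config$ring_width / px
    # cytoplasmic / membrane markers as full discs
    if (plan$amp_ck[i] > 0 || plan$amp_cd45[i] > 0 ||
        (config$m4_enabled && plan$amp_m4[i] > 0)) {
      idx <- ellipse_idx(h, w, cx, cy, r_cyto, r_cyto, 0)
      if (plan$amp_ck[i] > 0) m_ck[idx] <- m_ck[idx] + plan$amp_ck[i]
      if (plan$amp_cd45[i] > 0) m_cd45[idx] <- m_cd45[idx] + plan$amp_cd45[i]
      if (config$m4_enabled && plan$amp_m4[i] > 0) {
        m_m4[idx] <- m_m4[idx] + plan$amp_m4[i]
      }
    }
    # nucleus
    area <- 0L
    if (plan$n_frag[i] > 1L) {
      k <- plan$n_frag[i]
      fr <- runif(k, 1.6, 2.0) / px
      # fragments on a jittered ring inside the cytoplasm, kept pairwise
      # separated so each renders as its own connected component
      req_sep <- 2 * max(fr) + 3
      d <- min(max(0.45 * r_cyto, req_sep / (2 * sin(pi / k))), 0.62 * r_cyto)
      ang0 <- runif(1, 0, 2 * pi)
      angs <- ang0 + 2 * pi * (seq_len(k) - 1) / k
      fx <- cx + d * cos(angs); fy <- cy + d * sin(angs)
      for (j in seq_len(k)) {
        idx <- ellipse_idx(h, w, fx[j], fy[j], fr[j], fr[j], 0)
        m_dapi[idx] <- m_dapi[idx] + plan$amp_dapi[i]
        area <- area + length(idx)
      }
      cx_t <- mean(fx); cy_t <- mean(fy)
    } else {
      # condensed nuclei shrink below the classifier's WBC-relative
      # condensation bound (0.35 x typical WBC nuclear area)
      rr <- if (plan$condensed[i]) {
        sqrt(0.35) * config$wbc_nuclear_diameter[1] / 2 / px
      } else r
      ecc <- runif(1, 0, 0.15); phi <- runif(1, 0, pi)
      idx <- ellipse_idx(h, w, cx, cy, rr * (1 + ecc), rr / (1 + ecc), phi)
      m_dapi[idx] <- m_dapi[idx] + plan$amp_dapi[i]
      area <- length(idx)
      cx_t <- cx; cy_t <- cy
    }
    truth$x[cell_id] <- cx_t; truth$y[cell_id] <- cy_t
    truth$class[cell_id] <- cls
    truth$cluster_id[cell_id] <- plan$cluster_id[i]
    truth$nuclear_area_px[cell_id] <- area
    truth$dapi[cell_id] <- plan$amp_dapi[i]
    truth$ck[cell_id] <- plan$amp_ck[i]
    truth$cd45[cell_id] <- plan$amp_cd45[i]
    truth$m4[cell_id] <- plan$amp_m4[i]
  }
  debris_tab <- data.frame(x = debris_x, y = debris_y,
                           class = rep("debris", length(debris_x)),
                           stringsAsFactors = FALSE)
  # DAPI speckle artifacts (sub-minimum-area; exercise the size filter)
  n_speck <- if (config$speckle_rate > 0) rpois(1L, config$speckle_rate) else 0L
  if (n_speck > 0) {
    for (s in seq_len(n_speck)) {
      idx <- ellipse_idx(h, w, runif(1, 5, w - 5), runif(1, 5, h - 5),
                         0.6 / px, 0.6 / px, 0)
      m_dapi[idx] <- m_dapi[idx] + config$amplitudes$dapi * 1.5
    }
  }
  ch <- list(DAPI = m_dapi, CK = m_ck, CD45 = m_cd45)
  if (config$m4_enabled) ch$M4 <- m_m4
  # PSF + noise
  kern <- gaussian_kernel(config$psf_sigma / px)
  for (nm in chan_names) {
    m <- imageData(filter2(Image(ch[[nm]]), kern, boundary = "replicate"))
    m <- m + config$background_level[[nm]]
    if (config$shot_noise) {
      m <- matrix(rpois(length(m), pmax(m, 0)), h, w)
    }
    nsd <- config$noise_sd[[nm]]
    if (nsd > 0) m <- m + matrix(rnorm(length(m), 0, nsd), h, w)
    ch[[nm]] <- pmax(m, 0)
  }
  list(channels = ch, truth = truth, debris = debris_tab)
}

# ---- public API -----------------------------------------------------------

#' Generate one synthetic slide tile with ground truth
#'
#' Renders a desk-scale tile holding a retained fraction of `wbc_count`
#' white blood cells plus `n_clc` spiked cell-line control (CLC) cells of
#' the configured subtype mix. WBCs are CD45+/CK- with intact nuclei; CLC
#' subtypes follow their classification definitions (traditional: CK+,
#' CD45-, intact, large nucleus; small: nuclear size at or below WBC;
#' cluster: chains of 2-5 touching traditional cells with merged cytoplasm;
#' CK-negative: no CK signal; apoptotic: fragmented or condensed nucleus).
#'
#' @param config a [generator_config()].
#' @param n_clc nominal number of spiked CLCs (>= 0).
#' @param slide_index integer used to derive the per-slide child seed from
#'   `config$seed`; identical (config, n_clc, slide_index) is bit-identical.
#' @param slide_id,sample_id,operator_id,run_id,test_id identifiers stored
#'   in the slide metadata.
#' @return list with elements `slide` (a `slide_image`: named channel
#'   rasters, pixel size, identifiers, metadata) and `truth` (one row per
#'   rendered cell: `cell_id`, 0-based pixel `x`/`y`, `class`, `cluster_id`,
#'   `nuclear_area_px`, true per-channel amplitudes).
#' @export
#' @examples
#' cfg <- generator_config(tile_shape = c(256, 256), wbc_count = 60, seed = 7)
#' s <- generate_slide(cfg, n_clc = 3)
#' table(s$truth$class)
generate_slide <- function(config, n_clc, slide_index = 1L,
                           slide_id = sprintf("slide_%03d", slide_index),
                           sample_id = "sample_1", operator_id = "op_1",
                           run_id = "run_1", test_id = "test_1") {
  stopifnot(inherits(config, "generator_config"))
  if (n_clc < 0) ctc_error("ctcscope_config_error", "n_clc must be >= 0")
  with_seed(child_seed(config$seed, slide_index), {
    plan <- plan_cells(config, n_clc)
    plan <- place_cells(plan, config)
    rend <- render_slide(plan, config)
  })
  slide <- structure(list(
    channels = rend$channels,
    pixel_size = config$pixel_size,
    slide_id = slide_id, sample_id = sample_id, operator_id = operator_id,
    run_id = run_id, test_id = test_id,
    metadata = list(
      nominal_clc = n_clc,
      nominal_cells = config$wbc_count + n_clc,
      scale_factor = config$scale_factor,
      ml_per_slide = config$ml_per_slide,
      n_debris = nrow(rend$debris),
      seed = child_seed(config$seed, slide_index),
      unspiked = n_clc == 0
    )
  ), class = "slide_image")
  truth <- rend$truth
  attr(truth, "debris") <- rend$debris
  list(slide = slide, truth = truth)
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf("<slide_image %s> %d x %d px @ %.2f um/px; channels: %s\n",
              x$slide_id, nrow(x$channels[[1]]), ncol(x$channels[[1]]),
              x$pixel_size, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Generate a spike-in dilution series
#'
#' One slide per (concentration, replicate); metadata records the nominal
#' concentration and run/test/slide indices, with two consecutive
#' replicates forming one test (two slides per test, three tests per run).
#'
#' @param config a [generator_config()].
#' @param concentrations nominal CLCs per slide (non-negative integers).
#' @param slides_per_concentration replicate slides per concentration.
#' @param operator_id operator identifier stamped on all slides.
#' @return object of class `slide_dataset`: list with `slides` (list of
#'   generate_slide results) and `manifest` (one row per slide).
#' @export
generate_dilution_series <- function(config, concentrations,
                                     slides_per_concentration = 6L,
                                     operator_id = "op_1") {
  if (any(concentrations < 0)) {
    ctc_error("ctcscope_config_error", "concentrations must be non-negative")
  }
  slides <- list(); manifest <- list()
  idx <- 0L
  for (ci in seq_along(concentrations)) {
    for (rep in seq_len(slides_per_concentration)) {
      idx <- idx + 1L
      test <- ceiling(rep / 2L)
      res <- generate_slide(
        config, n_clc = concentrations[ci], slide_index = idx,
        slide_id = sprintf("c%03d_s%02d", concentrations[ci], rep),
        sample_id = sprintf("dilution_%d", concentrations[ci]),
        operator_id = operator_id, run_id = "run_1",
        test_id = sprintf("test_%d", test)
      )
      slides[[idx]] <- res
      manifest[[idx]] <- data.frame(
        slide_id = res$slide$slide_id, sample_id = res$slide$sample_id,
        operator_id = operator_id, run_id = "run_1",
        test_id = res$slide$test_id, replicate = rep,
        nominal_clc = concentrations[ci],
        nominal_cells = config$wbc_count + concentrations[ci],
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(slides = slides,
                 manifest = if (idx) do.call(rbind, manifest) else
                   data.frame(slide_id = character(0))),
            class = "slide_dataset")
}

#' Generate a healthy-donor cohort (WBC-only slides)
#'
#' All slides contain only WBCs plus optional non-cell confounders
#' (CK-positive acellular debris without a nucleus, DAPI speckle) to
#' exercise assay specificity.
#'
#' @param config a [generator_config()]; its `debris_rate` / `speckle_rate`
#'   control confounders.
#' @param n_samples number of donors.
#' @param slides_per_sample slides per donor (two in the standard design).
#' @return a `slide_dataset` (see [generate_dilution_series()]).
#' @export
generate_healthy_cohort <- function(config, n_samples, slides_per_sample = 2L) {
  if (n_samples < 1) ctc_error("ctcscope_config_error", "n_samples must be >= 1")
  slides <- list(); manifest <- list()
  idx <- 0L
  for (s in seq_len(n_samples)) {
    for (rep in seq_len(slides_per_sample)) {
      idx <- idx + 1L
      res <- generate_slide(
        config, n_clc = 0L, slide_index = idx,
        slide_id = sprintf("hd%02d_s%02d", s, rep),
        sample_id = sprintf("hd_%02d", s),
        test_id = "test_1"
      )
      slides[[idx]] <- res
      manifest[[idx]] <- data.frame(
        slide_id = res$slide$slide_id, sample_id = res$slide$sample_id,
        operator_id = "op_1", run_id = "run_1", test_id = "test_1",
        replicate = rep, nominal_clc = 0L,
        nominal_cells = config$wbc_count, stringsAsFactors = FALSE
      )
    }
  }
  structure(list(slides = slides, manifest = do.call(rbind, manifest)),
            class = "slide_dataset")
}

#' Generate the four-way precision study dataset
#'
#' Standard design: three operators, five runs in total (operator 1 runs on
#' three days, operators 2 and 3 on one day each), each run holding three
#' replicate tests of two slides, for each requested dilution.
#'
#' @param config a [generator_config()].
#' @param dilutions nominal CLCs per slide to test (the standard study uses
#'   25 and 300).
#' @return a `slide_dataset` whose manifest carries operator/run/test ids.
#' @export
generate_precision_study <- function(config, dilutions = c(25L, 300L)) {
  design <- data.frame(
    operator = c("op_1", "op_1", "op_1", "op_2", "op_3"),
    run = paste0("run_", 1:5), stringsAsFactors = FALSE
  )
  slides <- list(); manifest <- list()
  idx <- 0L
  for (d in dilutions) {
    for (ri in seq_len(nrow(design))) {
      for (test in 1:3) {
        for (rep in 1:2) {
          idx <- idx + 1L
          res <- generate_slide(
            config, n_clc = d, slide_index = idx,
            slide_id = sprintf("d%03d_%s_t%d_s%d", d, design$run[ri], test, rep),
            sample_id = sprintf("dilution_%d", d),
            operator_id = design$operator[ri], run_id = design$run[ri],
            test_id = sprintf("test_%d", test)
          )
          slides[[idx]] <- res
          manifest[[idx]] <- data.frame(
            slide_id = res$slide$slide_id, sample_id = res$slide$sample_id,
            operator_id = design$operator[ri], run_id = design$run[ri],
            test_id = sprintf("test_%d", test), replicate = rep,
            nominal_clc = d, nominal_cells = config$wbc_count + d,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  structure(list(slides = slides, manifest = do.call(rbind, manifest)),
            class = "slide_dataset")
}
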