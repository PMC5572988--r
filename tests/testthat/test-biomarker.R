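test_that("quantify_marker reports expression, z-scores and group medians", {
  cells <- data.frame(cell_id = 1:6, m4_mean = c(10, 12, 11, 50, 52, 48))
  out <- quantify_marker(cells, groups = rep(c("low", "high"), each = 3))
  expect_equal(out$expression, cells$m4_mean)
  expect_equal(mean(out$z), 0)
  expect_equal(sd(out$z), 1)
  gm <- attr(out, "group_medians")
  expect_equal(unname(gm[c("low", "high")]), c(11, 50))
  expect_error(quantify_marker(data.frame(cell_id = 1, m4_mean = NA_real_)),
               class = "ctcscope_input_error")
})

test_that("FISH spot counter recovers planted spot counts", {
  mk <- function(n, seed) {
    set.seed(seed)
    # spots inside a 4-um nucleus on a 64x64 patch at 0.2 um/px,
    # pairwise separated beyond the detector's resolution limit
    repeat {
      ang <- runif(n, 0, 2 * pi); rad <- sqrt(runif(n, 0.05, 0.8)) * 18
      x <- 31.5 + rad * cos(ang); y <- 31.5 + rad * sin(ang)
      if (n < 2 || min(dist(cbind(x, y))) > 6) break
    }
    render_fish_patch(spots = data.frame(x = x, y = y), seed = seed)
  }
  for (n in c(0L, 1L, 2L, 3L, 4L)) {
    p <- mk(n, seed = 100 + n)
    expect_identical(count_fish_signals(p$patch, p$mask), n)
  }
  p <- mk(2, seed = 7)
  expect_error(count_fish_signals(p$patch, p$mask[1:32, ]),
               class = "ctcscope_input_error")
  expect_error(count_fish_signals(p$patch, p$mask & FALSE),
               class = "ctcscope_input_error")
})

test_that("PTEN status follows the two-colour rule set", {
  out <- classify_pten_status(c(3, 2, 0, 4, 0), c(3, 4, 4, 2, 0))
  expect_equal(as.character(out$status),
               c("NON_DELETED", "HETEROZYGOUS_LOSS", "HOMOZYGOUS_LOSS",
                 "NON_DELETED", NA))
  expect_equal(out$polyploid, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_error(classify_pten_status(-1, 2), class = "ctcscope_input_error")
})

test_that("end-to-end FISH patches reproduce the worked status calls", {
  # (pten, cep10): (3,3) non-deleted; (2,4) heterozygous loss with
  # polyploidy; (0,4) homozygous loss with polyploidy
  spots_at <- function(k) {
    ang <- 2 * pi * seq_len(k) / max(k, 1) + 0.4
    data.frame(x = 31.5 + 12 * cos(ang), y = 31.5 + 12 * sin(ang))
  }
  count_pair <- function(np, nc, seed) {
    pp <- render_fish_patch(spots = spots_at(np), seed = seed)
    pc <- render_fish_patch(spots = spots_at(nc), seed = seed + 1)
    c(count_fish_signals(pp$patch, pp$mask), count_fish_signals(pc$patch, pc$mask))
  }
  cases <- list(c(3, 3), c(2, 4), c(0, 4))
  got <- t(vapply(seq_along(cases), function(i) {
    count_pair(cases[[i]][1], cases[[i]][2], seed = 50 + 10 * i)
  }, numeric(2)))
  expect_equal(got[, 1], c(3, 2, 0))
  expect_equal(got[, 2], c(3, 4, 4))
  st <- classify_pten_status(got[, 1], got[, 2])
  expect_equal(as.character(st$status),
               c("NON_DELETED", "HETEROZYGOUS_LOSS", "HOMOZYGOUS_LOSS"))
  expect_equal(st$polyploid, c(TRUE, TRUE, TRUE))
})
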