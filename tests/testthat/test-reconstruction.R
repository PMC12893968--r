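make_clutter_bubble_stack <- function(n_frames = 150L, grid = c(64L, 64L),
                                      seed = 1L) {
  tree <- vessel_tree(list(straight_segment(1600, 300, 2900, speed = 10)),
                      fov_um = grid * 50)
  gt <- simulate_mb_flow(tree, density = 1L, n_frames = n_frames,
                         frame_rate_hz = 80, seed = seed)
  set.seed(seed)
  clut <- matrix(stats::runif(prod(grid), 1, 3), grid[1], grid[2])
  list(gt = gt,
       full = render_frames(gt, grid_px = grid, clutter = clut, noise_sd = 0,
                            amplitude = 0.5, seed = seed),
       bubbles_only = render_frames(gt, grid_px = grid, clutter = 0,
                                    noise_sd = 0, amplitude = 0.5, seed = seed))
}

test_that("one SVD component absorbs perfectly static clutter", {
  set.seed(2)
  clut <- matrix(stats::runif(32 * 32), 32, 32)
  frames <- array(rep(clut, each = 20), dim = c(20, 32, 32))
  st <- frame_stack(frames, 80, 50)
  filt <- svd_clutter_filter(st, low_cut = 1L)
  expect_lt(sqrt(sum(filt$frames^2)) / sqrt(sum(st$frames^2)), 1e-8)
})

test_that("keeping every component reproduces the input", {
  set.seed(3)
  st <- frame_stack(array(stats::rnorm(20 * 16 * 16), c(20, 16, 16)), 80, 50)
  filt <- svd_clutter_filter(st, low_cut = 0L, high_cut = 20L)
  rel <- sqrt(sum((filt$frames - st$frames)^2)) / sqrt(sum(st$frames^2))
  expect_lt(rel, 1e-6)
})

test_that("retained and removed energy sum to the input energy", {
  set.seed(4)
  st <- frame_stack(array(stats::rnorm(15 * 12 * 12), c(15, 12, 12)), 80, 50)
  filt <- svd_clutter_filter(st, low_cut = 3L)
  removed <- st$frames - filt$frames
  expect_equal(sum(filt$frames^2) + sum(removed^2), sum(st$frames^2),
               tolerance = 1e-6)
})

test_that("filtering a clutter + bubble phantom recovers the bubble signal", {
  ph <- make_clutter_bubble_stack()
  filt <- svd_clutter_filter(ph$full, low_cut = 1L)
  ## removing the static subspace necessarily also removes the temporal mean
  ## of the bubble signal (the accumulated vessel ridge), so the ideal filter
  ## output is the mean-subtracted bubble-only render
  mean_img <- apply(ph$bubbles_only$frames, c(2, 3), mean)
  cors_ideal <- vapply(seq_len(150L), function(f)
    stats::cor(as.vector(filt$frames[f, , ]),
               as.vector(ph$bubbles_only$frames[f, , ] - mean_img)), numeric(1))
  expect_true(all(cors_ideal > 0.99))
  cors_raw <- vapply(seq_len(150L), function(f)
    stats::cor(as.vector(filt$frames[f, , ]),
               as.vector(ph$bubbles_only$frames[f, , ])), numeric(1))
  expect_true(all(cors_raw > 0.85))
})

test_that("rank-cut bounds and argument validation hold", {
  set.seed(5)
  st <- frame_stack(array(stats::rnorm(10 * 8 * 8), c(10, 8, 8)), 80, 50)
  expect_error(svd_clutter_filter(st, low_cut = 10L), "low_cut")
  expect_error(svd_clutter_filter(st, low_cut = 2L, high_cut = 2L), "high_cut")
  expect_error(svd_clutter_filter(st, low_cut = 2L, high_cut = 11L), "high_cut")
})

test_that("rank-cut suggestion finds the clutter gap", {
  expect_equal(suggest_rank_cut(c(100, 1, 1, 1)), 1L)
  expect_equal(suggest_rank_cut(c(100, 50, 1, 1, 1)), 2L)   # largest gap
  expect_equal(suggest_rank_cut(c(5, 5, 5, 5)), 1L)         # flat -> minimum
  expect_equal(suggest_rank_cut(c(5, 5, 5, 5), min_cut = 2L), 2L)
  expect_error(suggest_rank_cut(c(0, 0, 0)), "zero")
  expect_error(suggest_rank_cut(c(1, 2, 3)), "non-increasing")
})

test_that("detection applies threshold, area and eccentricity gates", {
  expect_equal(nrow(detect_microbubbles(matrix(0, 32, 32), threshold = 0.1)), 0L)

  one <- render_blob_frame(cbind(800, 900), grid_px = c(32L, 32L))
  d1 <- detect_microbubbles(one, threshold = 0.5, area_max_px = 200L)
  expect_equal(nrow(d1), 1L)
  expect_false(d1$touches_border)
  expect_lt(d1$eccentricity, 0.3)

  # elongated artifact beyond the eccentricity gate is rejected
  art <- matrix(0, 32, 32); art[16, 5:28] <- 1
  d2 <- detect_microbubbles(art, threshold = 0.5, area_max_px = 200L,
                            ecc_max = 0.9)
  expect_equal(nrow(d2), 0L)
  d3 <- detect_microbubbles(art, threshold = 0.5, area_max_px = 200L,
                            ecc_max = 0.9999)
  expect_equal(nrow(d3), 1L)
  expect_gt(d3$eccentricity, 0.98)

  # area gates
  small <- matrix(0, 16, 16); small[8, 8] <- 1
  expect_equal(nrow(detect_microbubbles(small, threshold = 0.5,
                                        area_min_px = 2L)), 0L)
  expect_equal(nrow(detect_microbubbles(small, threshold = 0.5,
                                        area_min_px = 1L)), 1L)

  # 8-connectivity: a diagonal chain is one component
  diag2 <- matrix(0, 16, 16)
  diag2[cbind(5:8, 5:8)] <- 1
  d4 <- detect_microbubbles(diag2, threshold = 0.5, ecc_max = 0.9999)
  expect_equal(nrow(d4), 1L)
  expect_equal(d4$area_px, 4L)
})

test_that("intensity-weighted centroids are exact on constructed blobs", {
  # symmetric blob centred on a pixel
  f <- render_blob_frame(cbind(5 * 50, 7 * 50), grid_px = c(16L, 16L))
  d <- detect_microbubbles(f, threshold = 0.3, area_max_px = 200L)
  loc <- localize_centroid(f, d[1, ], 50)
  expect_equal(loc$axial_um / 50, 5, tolerance = 1e-9)
  expect_equal(loc$lateral_um / 50, 7, tolerance = 1e-9)

  # two-pixel weighted mean: weights 1 and 3 one pixel apart
  g <- matrix(0, 8, 8); g[3, 3] <- 1; g[3, 4] <- 3
  det <- list(pixels = cbind(c(3, 3), c(3, 4)))
  loc2 <- localize_centroid(g, det, 50)
  expect_equal(loc2$axial_um / 50, 2.0)
  expect_equal(loc2$lateral_um / 50, 2.75)

  zero <- list(pixels = cbind(2, 2))
  expect_error(localize_centroid(matrix(0, 4, 4), zero, 50), "zero total")
})

test_that("density accumulation conserves localization counts", {
  locs <- data.frame(axial_um = rep(1000, 7), lateral_um = rep(1500, 7))
  m <- accumulate_density_map(locs, c(64L, 64L), 50, 10L)
  expect_equal(sum(m$counts), 7)
  expect_equal(max(m$counts), 7)              # one bin takes them all

  empty <- accumulate_density_map(locs[0, ], c(64L, 64L), 50, 10L)
  expect_true(all(empty$counts == 0))

  out <- data.frame(axial_um = -100, lateral_um = 10)
  expect_error(accumulate_density_map(out, c(64L, 64L), 50, 10L),
               "outside the field of view")
})

test_that("SR counts concentrate around the true centreline", {
  grid <- c(64L, 64L)
  tree <- vessel_tree(list(straight_segment(1600, 300, 2900, speed = 10,
                                            radius_um = 50)),
                      fov_um = grid * 50)
  gt <- simulate_mb_flow(tree, density = 2L, n_frames = 150L, seed = 8L)
  st <- render_frames(gt, grid_px = grid, clutter = 2, clutter_drift_amp = 0.03,
                      noise_sd = 0.01, amplitude = 1, seed = 8L)
  filt <- svd_clutter_filter(st, low_cut = 2L)
  locs <- localize_stack(filt, threshold = 0.25, area_max_px = 200L)
  m <- accumulate_density_map(locs, grid, 50, 10L)
  occ <- which(m$counts > 0, arr.ind = TRUE)
  ## distance of each occupied SR bin centre to the centreline (a horizontal
  ## line at axial 1600 um between lateral 300 and 2900)
  ax <- (occ[, 1] - 1) * m$spacing_um - 25 + m$spacing_um / 2
  lt <- (occ[, 2] - 1) * m$spacing_um - 25 + m$spacing_um / 2
  dist <- abs(ax - 1600)
  dist[lt < 300] <- sqrt((ax[lt < 300] - 1600)^2 + (lt[lt < 300] - 300)^2)
  dist[lt > 2900] <- sqrt((ax[lt > 2900] - 1600)^2 + (lt[lt > 2900] - 2900)^2)
  w <- m$counts[occ]
  frac <- sum(w[dist <= 50 + m$spacing_um]) / sum(w)
  expect_gte(frac, 0.9)
})

test_that("detection count equals truth for well-separated noiseless bubbles", {
  grid <- c(64L, 64L)
  segs <- list(straight_segment(800, 300, 2900, speed = 8, radius_um = 1),
               straight_segment(2400, 300, 2900, speed = 8, radius_um = 1))
  tree <- vessel_tree(segs, fov_um = grid * 50)  # separation >> 4 PSF sigma
  gt <- simulate_mb_flow(tree, density = 1L, n_frames = 20L, seed = 9L)
  st <- render_frames(gt, grid_px = grid, clutter = 0, noise_sd = 0)
  for (f in seq_len(20L)) {
    det <- detect_microbubbles(st$frames[f, , ], threshold = 0.5,
                               area_max_px = 200L)
    expect_equal(nrow(det), 2L)
  }
})

test_that("localization error shrinks monotonically with SNR", {
  set.seed(10)
  rows <- (0:63) * 50; cols <- (0:63) * 50
  rmse_at <- function(noise_sd) {
    err2 <- numeric(0)
    while (length(err2) < 120) {
      pos <- cbind(stats::runif(3, 400, 2800), stats::runif(3, 400, 2800))
      if (min(stats::dist(pos)) < 700) next
      img <- matrix(0, 64, 64)
      for (k in 1:3)
        img <- img + exp(-(rows - pos[k, 1])^2 / (2 * 150^2)) %o%
                     exp(-(cols - pos[k, 2])^2 / (2 * 150^2))
      img <- img + matrix(stats::rnorm(64 * 64, 0, noise_sd), 64, 64)
      det <- detect_microbubbles(img, threshold = 0.5, area_max_px = 200L)
      if (!nrow(det)) next
      locs <- do.call(rbind, lapply(seq_len(nrow(det)), function(i)
        localize_centroid(img, det[i, ], 50)))
      for (k in 1:3)
        err2 <- c(err2, min((locs$axial_um - pos[k, 1])^2 +
                            (locs$lateral_um - pos[k, 2])^2))
    }
    sqrt(mean(err2))
  }
  r <- vapply(c(0.3, 0.1, 0.03), rmse_at, numeric(1))  # 10 / 20 / 30 dB
  expect_true(r[1] > r[2] && r[2] > r[3])
})

test_that("automatic noise-floor cut keeps the signal subspace", {
  set.seed(11)
  clut <- matrix(stats::runif(24 * 24, 5, 6), 24, 24)
  sig <- outer(sin(1:24), cos(1:24)) / 4
  frames <- array(0, c(40, 24, 24))
  for (f in 1:40)
    frames[f, , ] <- clut + sig * sin(f) +
      matrix(stats::rnorm(576, 0, 1e-3), 24, 24)
  st <- frame_stack(frames, 80, 50)
  filt <- svd_clutter_filter(st, low_cut = 1L, high_cut = "auto")
  cuts <- attr(filt, "cuts")
  ## the cut falls after the two structured components but before the
  ## 38-component noise floor
  expect_gte(cuts["high_cut"], 2)
  expect_lt(cuts["high_cut"], 40)
  ## the oscillating signal survives the cut (frame 2: sin(2) > 0)
  expect_gt(stats::cor(as.vector(filt$frames[2, , ]), as.vector(sig)), 0.9)
})
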