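# Shared fixture builders and independent oracles, all generated in code.

# straight horizontal vessel at a given depth
straight_segment <- function(axial_um, from_um, to_um, radius_um = 50,
                             speed = 10, n_pts = 101L) {
  list(centerline = cbind(axial_um = rep(axial_um, n_pts),
                          lateral_um = seq(from_um, to_um, length.out = n_pts)),
       radius_um = radius_um, flow_speed_mm_s = speed)
}

# semicircular centreline of radius R centred at (ca, cl)
semicircle_segment <- function(ca, cl, R, radius_um = 50, speed = 10,
                               n_pts = 401L) {
  th <- seq(0, pi, length.out = n_pts)
  list(centerline = cbind(axial_um = ca + R * sin(th),
                          lateral_um = cl + R * cos(th)),
       radius_um = radius_um, flow_speed_mm_s = speed)
}

# render a single frame with Gaussian blobs at given (axial_um, lateral_um)
render_blob_frame <- function(pos_um, grid_px = c(64L, 64L),
                              pixel_size_um = 50, sigma_um = 150,
                              amplitude = 1) {
  rows <- (seq_len(grid_px[1]) - 1L) * pixel_size_um
  cols <- (seq_len(grid_px[2]) - 1L) * pixel_size_um
  img <- matrix(0, grid_px[1], grid_px[2])
  for (k in seq_len(nrow(pos_um))) {
    gr <- exp(-(rows - pos_um[k, 1])^2 / (2 * sigma_um^2))
    gc <- exp(-(cols - pos_um[k, 2])^2 / (2 * sigma_um^2))
    img <- img + amplitude * outer(gr, gc)
  }
  img
}

# exhaustive optimal one-to-one assignment among gated candidates:
# maximize the number of pairs, then minimize total displacement.
# cand: data.frame i, j, dist (already gate-filtered). Returns a data.frame
# of the optimal pairs sorted by i.
optimal_assignment <- function(cand, n_i) {
  best <- list(npairs = -1L, total = Inf, pairs = NULL)
  rec <- function(i, used_j, acc) {
    if (i > n_i) {
      np <- if (is.null(acc)) 0L else nrow(acc)
      tot <- if (np) sum(acc$dist) else 0
      if (np > best$npairs || (np == best$npairs && tot < best$total))
        best <<- list(npairs = np, total = tot, pairs = acc)
      return(invisible())
    }
    opts <- cand[cand$i == i & !(cand$j %in% used_j), , drop = FALSE]
    rec(i + 1L, used_j, acc)                 # leave i unmatched
    for (r in seq_len(nrow(opts)))
      rec(i + 1L, c(used_j, opts$j[r]), rbind(acc, opts[r, ]))
  }
  rec(1L, integer(0), NULL)
  p <- best$pairs
  if (is.null(p)) return(data.frame(i = integer(0), j = integer(0)))
  p[order(p$i), c("i", "j")]
}

# right-angle Sierpinski triangle raster after k subdivisions
sierpinski_raster <- function(k = 5L) {
  s <- matrix(1L, 1L, 1L)
  for (i in seq_len(k)) {
    z <- matrix(0L, nrow(s), ncol(s))
    s <- rbind(cbind(s, z), cbind(s, s))
  }
  s
}

# mb_track along an analytic curve sampled at given times
track_from_curve <- function(fx, fy, t, frame_rate_hz = 80) {
  mb_track(seq_along(t), fx(t), fy(t), frame_rate_hz)
}

# disc ROI mask on an n x n frame grid
disc_mask <- function(n, cr, cc, rad) {
  idx <- expand.grid(r = seq_len(n), c = seq_len(n))
  m <- matrix(0, n, n)
  m[as.matrix(idx[ (idx$r - cr)^2 + (idx$c - cc)^2 <= rad^2, ])] <- 1
  m
}
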