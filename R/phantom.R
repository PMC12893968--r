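#' @title Synthetic phantom generator
#' @description Vessel trees, flowing microbubbles, rendered contrast frame
#'   stacks, bolus time-intensity curves and two-group lesion cohorts with
#'   known ground truth, so every downstream stage is testable without any
#'   patient data.
#' @name phantom
NULL

## ---- vessel trees ----------------------------------------------------------

## internal: polyline path length, chord length, tortuosity
polyline_tortuosity <- function(xy) {
  steps <- sqrt(rowSums(diff(xy)^2))
  path <- sum(steps)
  chord <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
  list(path_um = path, chord_um = chord,
       tortuosity = if (chord > 0) path / chord else NA_real_)
}

#' Construct a vessel tree from explicit segments
#'
#' Each segment is a centreline polyline (columns axial_um, lateral_um), a
#' radius and a signed flow speed along the polyline direction. True
#' tortuosity (path length / chord length) is computed from the polyline
#' and stored, so reconstruction accuracy can be judged against it.
#'
#' @param segments list; each element a list with `centerline` (n x 2 matrix,
#'   columns axial_um, lateral_um), `radius_um` (> 0), `flow_speed_mm_s` (> 0).
#' @param fov_um length-2 field of view (axial, lateral) in micrometres.
#' @return Object of class `vessel_tree`.
#' @export
vessel_tree <- function(segments, fov_um) {
  stopifnot(length(segments) >= 1L, length(fov_um) == 2L, all(fov_um > 0))
  segments <- lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    cl <- s$centerline
    if (!is.matrix(cl) || ncol(cl) != 2L || nrow(cl) < 2L)
      stop("segment ", i, ": centerline must be an n x 2 matrix with n >= 2")
    if (s$radius_um <= 0) stop("segment ", i, ": radius must be positive")
    if (s$flow_speed_mm_s < 0) stop("segment ", i, ": flow speed must be non-negative")
    if (any(cl[, 1] < 0 | cl[, 1] > fov_um[1] |
            cl[, 2] < 0 | cl[, 2] > fov_um[2]))
      stop("segment ", i, ": centerline leaves the field of view")
    tt <- polyline_tortuosity(cl)
    list(centerline = cl, radius_um = s$radius_um,
         flow_speed_mm_s = s$flow_speed_mm_s,
         path_um = tt$path_um, chord_um = tt$chord_um,
         tortuosity_true = tt$tortuosity)
  })
  structure(list(segments = segments, fov_um = as.numeric(fov_um)),
            class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %d segments in %.3g x %.3g mm FOV\n",
              length(x$segments), x$fov_um[1] / 1e3, x$fov_um[2] / 1e3))
  for (i in seq_along(x$segments)) {
    s <- x$segments[[i]]
    cat(sprintf("  [%d] r=%.3g um, v=%.3g mm/s, tortuosity=%.4f\n",
                i, s$radius_um, s$flow_speed_mm_s, s$tortuosity_true))
  }
  invisible(x)
}

## internal: sample a circular-arc polyline. arc_frac = fraction of a full
## semicircle bent into the vessel (0 -> straight).
arc_polyline <- function(start_um, heading, length_um, arc_frac, n_pts = 201L) {
  t <- seq(0, 1, length.out = n_pts)
  if (arc_frac < 1e-9) {
    ax <- start_um[1] + t * length_um * sin(heading)
    lt <- start_um[2] + t * length_um * cos(heading)
  } else {
    phi <- arc_frac * pi               # total turned angle
    R <- length_um / phi               # arc length preserved
    ang <- heading + t * phi
    ax <- start_um[1] + R * (cos(heading) - cos(ang))
    lt <- start_um[2] + R * (sin(ang) - sin(heading))
  }
  cbind(axial_um = ax, lateral_um = lt)
}

#' Generate a random vessel tree
#'
#' Segments are circular arcs with random start points and headings;
#' curvature, radius and speed are drawn uniformly from the supplied
#' ranges. A draw whose centreline would leave the field of view is
#' re-attempted; if no placement fits the configuration is rejected.
#'
#' @param n_segments number of vessel segments.
#' @param fov_um length-2 field of view (axial, lateral), micrometres.
#' @param length_um segment arc length, micrometres (scalar or range);
#'   default 45-75% of the shorter field-of-view side.
#' @param radius_um vessel radius range, micrometres.
#' @param flow_speed_mm_s flow speed range, mm/s.
#' @param arc_frac curvature range as a fraction of a semicircle
#'   (0 = straight, 1 = full semicircle).
#' @param seed integer seed; the tree is deterministic given it.
#' @param max_tries placement attempts per segment before rejecting.
#' @return Object of class `vessel_tree`.
#' @export
make_vessel_tree <- function(n_segments = 3L, fov_um = c(6400, 6400),
                             length_um = NULL,
                             radius_um = c(40, 120),
                             flow_speed_mm_s = c(5, 20),
                             arc_frac = c(0, 0.6),
                             seed = 1L, max_tries = 200L) {
  stopifnot(n_segments >= 1L)
  if (is.null(length_um)) length_um <- c(0.45, 0.75) * min(fov_um)
  rng <- function(x) if (length(x) == 1L) c(x, x) else x
  length_um <- rng(length_um); radius_um <- rng(radius_um)
  flow_speed_mm_s <- rng(flow_speed_mm_s); arc_frac <- rng(arc_frac)
  set.seed(as.integer(seed))
  segs <- vector("list", n_segments)
  for (i in seq_len(n_segments)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r <- stats::runif(1, radius_um[1], radius_um[2])
      start <- c(stats::runif(1, 0.1, 0.9) * fov_um[1],
                 stats::runif(1, 0.1, 0.9) * fov_um[2])
      cl <- arc_polyline(start, stats::runif(1, 0, 2 * pi),
                         stats::runif(1, length_um[1], length_um[2]),
                         stats::runif(1, arc_frac[1], arc_frac[2]))
      ## keep the full lumen (centreline +/- radius) inside the FOV
      if (all(cl[, 1] >= r & cl[, 1] <= fov_um[1] - r &
              cl[, 2] >= r & cl[, 2] <= fov_um[2] - r)) {
        segs[[i]] <- list(centerline = cl,
                          radius_um = r,
                          flow_speed_mm_s = stats::runif(1, flow_speed_mm_s[1],
                                                         flow_speed_mm_s[2]))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place segment ", i, " inside the field of view; ",
           "reduce curvature or segment length")
  }
  vessel_tree(segs, fov_um)
}

## ---- microbubble flow ------------------------------------------------------

#' Simulate microbubble flow along a vessel tree
#'
#' Bubbles are advected along segment centrelines at the segment flow speed,
#' with a fixed perpendicular offset within the vessel radius; a bubble
#' reaching the end of its segment respawns at the start (keeping the
#' density stationary). The stored per-bubble velocity is the discrete
#' forward difference (displacement x frame rate), so positions and
#' velocities are exactly consistent; respawn steps are flagged.
#'
#' @param tree a `vessel_tree`.
#' @param density bubbles per segment.
#' @param n_frames number of frames (>= 2).
#' @param frame_rate_hz frame rate in Hz.
#' @param seed integer seed.
#' @return Object of class `mb_ground_truth`: a data.frame `positions` with
#'   columns frame, bubble_id, segment, axial_um, lateral_um, v_axial_mm_s,
#'   v_lateral_mm_s, respawn; plus frame_rate_hz and the tree.
#' @export
simulate_mb_flow <- function(tree, density = 2L, n_frames = 200L,
                             frame_rate_hz = 80, seed = 1L) {
  stopifnot(inherits(tree, "vessel_tree"), n_frames >= 2L, frame_rate_hz > 0,
            density >= 1L)
  set.seed(as.integer(seed))
  dt <- 1 / frame_rate_hz
  out <- vector("list", length(tree$segments))
  bub_id <- 0L
  for (si in seq_along(tree$segments)) {
    seg <- tree$segments[[si]]
    step_um <- seg$flow_speed_mm_s * 1e3 * dt
    if (step_um > seg$path_um)
      stop("segment ", si, ": per-frame displacement (", round(step_um, 1),
           " um) exceeds segment length - undersampled phantom")
    cl <- seg$centerline
    cum <- c(0, cumsum(sqrt(rowSums(diff(cl)^2))))
    ## unit tangent/normal per vertex interval for perpendicular offsets
    interp <- function(s) {
      s <- s %% seg$path_um
      j <- findInterval(s, cum, rightmost.closed = TRUE)
      j <- pmin(pmax(j, 1L), nrow(cl) - 1L)
      f <- (s - cum[j]) / (cum[j + 1] - cum[j])
      tang <- cl[j + 1, , drop = FALSE] - cl[j, , drop = FALSE]
      tang <- tang / sqrt(rowSums(tang^2))
      pos <- cl[j, , drop = FALSE] + f * (cl[j + 1, , drop = FALSE] - cl[j, , drop = FALSE])
      list(pos = pos, normal = cbind(-tang[, 2], tang[, 1]))
    }
    for (b in seq_len(density)) {
      bub_id <- bub_id + 1L
      s0 <- stats::runif(1, 0, seg$path_um)
      off <- stats::runif(1, -1, 1) * seg$radius_um
      s_t <- s0 + (seq_len(n_frames) - 1L) * step_um
      it <- interp(s_t)
      pos <- it$pos + off * it$normal
      respawn <- c(diff(s_t %% seg$path_um) < 0, FALSE)
      v_ax <- c(diff(pos[, 1]), NA) * frame_rate_hz * 1e-3
      v_lt <- c(diff(pos[, 2]), NA) * frame_rate_hz * 1e-3
      ## last frame: carry the previous step's velocity forward
      nlast <- n_frames
      v_ax[nlast] <- v_ax[nlast - 1L]; v_lt[nlast] <- v_lt[nlast - 1L]
      out[[length(out) + 1L]] <- data.frame(
        frame = seq_len(n_frames), bubble_id = bub_id, segment = si,
        axial_um = pos[, 1], lateral_um = pos[, 2],
        v_axial_mm_s = v_ax, v_lateral_mm_s = v_lt, respawn = respawn)
    }
  }
  positions <- do.call(rbind, out)
  rownames(positions) <- NULL
  structure(list(positions = positions, frame_rate_hz = frame_rate_hz,
                 tree = tree),
            class = "mb_ground_truth")
}

#' @export
print.mb_ground_truth <- function(x, ...) {
  cat(sprintf("<mb_ground_truth> %d bubbles x %d frames at %g Hz\n",
              length(unique(x$positions$bubble_id)),
              max(x$positions$frame), x$frame_rate_hz))
  invisible(x)
}

## ---- frame rendering -------------------------------------------------------

#' Render a contrast frame stack from microbubble ground truth
#'
#' Each frame is tissue clutter (a static image, optionally modulated by a
#' slow sinusoidal gain drift so the clutter subspace has rank <= 2) plus an
#' isotropic Gaussian point-spread function at every bubble position, plus
#' i.i.d. Gaussian noise. The clutter model is deliberately low-rank so the
#' SVD filtering stage is analytically checkable.
#'
#' @param gt `mb_ground_truth` from [simulate_mb_flow()].
#' @param grid_px length-2 grid size (rows, cols) in pixels.
#' @param pixel_size_um pixel pitch, micrometres.
#' @param psf_sigma_um Gaussian PSF standard deviation, micrometres
#'   (must be >= pixel_size_um / 2 so bubbles are not aliased).
#' @param amplitude peak PSF amplitude per bubble.
#' @param clutter static clutter image (matrix matching `grid_px`), a single
#'   number for uniform clutter, or 0 for none.
#' @param clutter_drift_amp relative amplitude of a slow sinusoidal gain
#'   drift applied to the clutter (0 = static).
#' @param clutter_drift_hz drift frequency, Hz.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer seed (noise only; positions come from `gt`).
#' @return A `frame_stack`.
#' @export
render_frames <- function(gt, grid_px = c(128L, 128L), pixel_size_um = 50,
                          psf_sigma_um = 150, amplitude = 1,
                          clutter = 0, clutter_drift_amp = 0,
                          clutter_drift_hz = 1, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(gt, "mb_ground_truth"), noise_sd >= 0)
  if (psf_sigma_um < pixel_size_um / 2)
    stop("`psf_sigma_um` must be at least pixel_size_um / 2")
  nr <- grid_px[1]; nc <- grid_px[2]
  nf <- max(gt$positions$frame)
  if (is.matrix(clutter)) {
    if (!all(dim(clutter) == grid_px)) stop("clutter image does not match grid")
    clut <- clutter
  } else clut <- matrix(clutter, nr, nc)
  set.seed(as.integer(seed))
  frames <- array(0, dim = c(nf, nr, nc))
  rows_um <- (seq_len(nr) - 1L) * pixel_size_um
  cols_um <- (seq_len(nc) - 1L) * pixel_size_um
  pos <- split(gt$positions, gt$positions$frame)
  half_win <- ceiling(4 * psf_sigma_um / pixel_size_um)
  for (f in seq_len(nf)) {
    img <- clut * (1 + clutter_drift_amp *
                     sin(2 * pi * clutter_drift_hz * (f - 1) / gt$frame_rate_hz))
    p <- pos[[as.character(f)]]
    if (!is.null(p)) for (k in seq_len(nrow(p))) {
      r0 <- round(p$axial_um[k] / pixel_size_um)
      c0 <- round(p$lateral_um[k] / pixel_size_um)
      rr <- max(1L, r0 + 1L - half_win):min(nr, r0 + 1L + half_win)
      cc <- max(1L, c0 + 1L - half_win):min(nc, c0 + 1L + half_win)
      if (!length(rr) || !length(cc)) next
      gr <- exp(-((rows_um[rr] - p$axial_um[k])^2) / (2 * psf_sigma_um^2))
      gc <- exp(-((cols_um[cc] - p$lateral_um[k])^2) / (2 * psf_sigma_um^2))
      img[rr, cc] <- img[rr, cc] + amplitude * outer(gr, gc)
    }
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
    frames[f, , ] <- img
  }
  frame_stack(frames, gt$frame_rate_hz, pixel_size_um)
}

## ---- time-intensity curves -------------------------------------------------

#' Simulate a bolus time-intensity curve
#'
#' A piecewise-linear bolus: flat baseline until contrast arrival, linear
#' wash-in to the peak over `ttp_s`, then linear wash-out at `washout_rate`
#' (floored at baseline). All true parameters are available in closed form
#' and stored with the curve: relative peak intensity
#' PI = (peak - baseline) / baseline, time to peak, wash-in slope
#' peak_amp / ttp_s, wash-out slope -washout_rate, and the exact area under
#' the continuous curve over the record.
#'
#' @param baseline pre-contrast intensity (> 0; PI divides by it).
#' @param peak_amp enhancement above baseline at the peak.
#' @param arrival_s contrast arrival time, seconds.
#' @param ttp_s time from arrival to peak, seconds.
#' @param washout_rate magnitude of the post-peak slope, intensity/s (> 0).
#' @param duration_s record length, seconds.
#' @param sample_hz sampling rate, Hz.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer seed.
#' @return Object of class `tic_curve` with fields time_s, intensity and a
#'   `truth` list of the generating parameters.
#' @export
simulate_tic <- function(baseline = 10, peak_amp = 30, arrival_s = 10,
                         ttp_s = 10, washout_rate = 1, duration_s = 60,
                         sample_hz = 10, noise_sd = 0, seed = 1L) {
  if (baseline <= 0) stop("`baseline` must be positive (PI divides by it)")
  stopifnot(peak_amp > 0, ttp_s > 0, washout_rate > 0)
  if (!(arrival_s < arrival_s + ttp_s && arrival_s + ttp_s < duration_s))
    stop("need arrival_s < arrival_s + ttp_s < duration_s")
  set.seed(as.integer(seed))
  t <- seq(0, duration_s, by = 1 / sample_hz)
  t_peak <- arrival_s + ttp_s
  y <- ifelse(t < arrival_s, baseline,
        ifelse(t < t_peak, baseline + peak_amp * (t - arrival_s) / ttp_s,
               pmax(baseline, baseline + peak_amp - washout_rate * (t - t_peak))))
  ## exact area of the continuous piecewise-linear curve over [0, duration]
  t_floor <- t_peak + peak_amp / washout_rate     # where decay meets baseline
  dec_end <- min(t_floor, duration_s)
  h_end <- max(0, peak_amp - washout_rate * (dec_end - t_peak))
  auc <- baseline * duration_s +                  # baseline pedestal
    0.5 * peak_amp * ttp_s +                      # wash-in triangle
    0.5 * (peak_amp + h_end) * (dec_end - t_peak) # wash-out trapezoid
  if (noise_sd > 0) y <- y + stats::rnorm(length(t), 0, noise_sd)
  structure(list(time_s = t, intensity = y,
                 truth = list(baseline = baseline, pi = peak_amp / baseline,
                              ttp_s = ttp_s, arrival_s = arrival_s,
                              auc = auc, wash_in_rate = peak_amp / ttp_s,
                              wash_out_rate = -washout_rate)),
            class = "tic_curve")
}

#' @export
print.tic_curve <- function(x, ...) {
  cat(sprintf("<tic_curve> %d samples over %.3g s\n",
              length(x$time_s), max(x$time_s)))
  invisible(x)
}

#' @export
plot.tic_curve <- function(x, ...) {
  plot(x$time_s, x$intensity, type = "l", xlab = "time (s)",
       ylab = "ROI mean intensity", ...)
  invisible(x)
}

## ---- lesion cohorts --------------------------------------------------------

#' Specify a two-group lesion cohort
#'
#' @param n_pos,n_neg group sizes (>= 2), HER2-positive and HER2-negative.
#' @param continuous named list; each element
#'   `list(mean = c(pos, neg), sd = c(pos, neg))`.
#' @param categorical named list; each element
#'   `list(levels = chr, p_pos = num, p_neg = num)` with probabilities
#'   summing to 1.
#' @param seed integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pos, n_neg, continuous = list(),
                        categorical = list(), seed = 1L) {
  stopifnot(n_pos >= 2L, n_neg >= 2L)
  for (nm in names(continuous)) {
    f <- continuous[[nm]]
    if (length(f$mean) != 2L || length(f$sd) != 2L || any(f$sd < 0))
      stop("continuous feature '", nm, "': need mean = c(pos, neg), sd >= 0")
  }
  for (nm in names(categorical)) {
    f <- categorical[[nm]]
    if (abs(sum(f$p_pos) - 1) > 1e-8 || abs(sum(f$p_neg) - 1) > 1e-8)
      stop("categorical feature '", nm, "': probabilities must sum to 1")
    if (length(f$levels) != length(f$p_pos) ||
        length(f$levels) != length(f$p_neg))
      stop("categorical feature '", nm, "': levels/probabilities mismatch")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 continuous = continuous, categorical = categorical,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default cohort specification
#'
#' Group means, spreads and category proportions follow the published
#' HER2-positive (n = 23) vs HER2-negative (n = 49) breast-lesion summaries:
#' lump diameter 3.78 +/- 1.38 vs 3.07 +/- 1.34 cm, and the reported
#' proportions for orientation, microcalcification, area of enhancement,
#' microvascular distribution and flow direction. Spreads of features
#' reported as median (IQR) are converted assuming normality (sd = IQR/1.35).
#'
#' @param n_pos,n_neg group sizes; defaults are the published 23 / 49.
#' @param seed integer seed.
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(n_pos = 23L, n_neg = 49L, seed = 1L) {
  cohort_spec(
    n_pos, n_neg,
    continuous = list(
      max_diameter_cm   = list(mean = c(3.78, 3.07), sd = c(1.38, 1.34)),
      pi                = list(mean = c(24.4, 18.7), sd = c(8.2, 10.9)),
      wash_in_rate      = list(mean = c(1.17, 0.88), sd = c(0.37, 0.39)),
      mean_tortuosity   = list(mean = c(3.0, 3.3),  sd = c(0.67, 0.44)),
      max_flow_velocity = list(mean = c(20.0, 18.0), sd = c(11.0, 2.3))),
    categorical = list(
      orientation = list(levels = c("parallel", "vertical"),
                         p_pos = c(20, 3) / 23, p_neg = c(29, 20) / 49),
      microcalcification = list(levels = c("no", "yes"),
                                p_pos = c(8, 15) / 23, p_neg = c(33, 16) / 49),
      area_of_enhancement = list(levels = c("unchanged", "larger"),
                                 p_pos = c(5, 18) / 23, p_neg = c(47, 2) / 49),
      mv_distribution = list(levels = c("central", "peripheral", "diffuse"),
                             p_pos = c(1, 12, 10) / 23,
                             p_neg = c(6, 35, 8) / 49),
      mv_flow_direction = list(levels = c("toward", "away"),
                               p_pos = c(5, 18) / 23, p_neg = c(33, 16) / 49)),
    seed = seed)
}

#' Simulate a lesion cohort
#'
#' Continuous features are drawn from per-group normal distributions and
#' categorical features from per-group multinomials, independently across
#' features; the HER2 label column is included. Deterministic per seed.
#'
#' @param spec a `cohort_spec`.
#' @return data.frame with one row per lesion and a `her2` factor column
#'   (levels negative, positive).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_pos + spec$n_neg
  her2 <- factor(rep(c("positive", "negative"), c(spec$n_pos, spec$n_neg)),
                 levels = c("negative", "positive"))
  out <- data.frame(lesion_id = seq_len(n), her2 = her2)
  pos <- her2 == "positive"
  for (nm in names(spec$continuous)) {
    f <- spec$continuous[[nm]]
    v <- numeric(n)
    v[pos]  <- stats::rnorm(spec$n_pos, f$mean[1], f$sd[1])
    v[!pos] <- stats::rnorm(spec$n_neg, f$mean[2], f$sd[2])
    out[[nm]] <- v
  }
  for (nm in names(spec$categorical)) {
    f <- spec$categorical[[nm]]
    v <- character(n)
    v[pos]  <- sample(f$levels, spec$n_pos, replace = TRUE, prob = f$p_pos)
    v[!pos] <- sample(f$levels, spec$n_neg, replace = TRUE, prob = f$p_neg)
    out[[nm]] <- factor(v, levels = f$levels)
  }
  out
}
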