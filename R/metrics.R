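#' @title Quantitative microvascular metrics
#' @description ROI velocity statistics, distance-metric tortuosity,
#'   skeleton-based vessel diameters, box-counting fractal dimension,
#'   microvascular density, and the two qualitative map features
#'   (distribution pattern, flow direction).
#' @name metrics
NULL

## internal: is a um position inside a frame-grid ROI mask?
roi_contains <- function(roi_mask, axial_um, lateral_um, pixel_size_um) {
  r <- round(axial_um / pixel_size_um) + 1L
  c <- round(lateral_um / pixel_size_um) + 1L
  ok <- r >= 1L & r <= nrow(roi_mask) & c >= 1L & c <= ncol(roi_mask)
  ins <- logical(length(r))
  ins[ok] <- roi_mask[cbind(r[ok], c[ok])] > 0
  ins
}

## internal: logical vector, one per step, TRUE when the step midpoint is in ROI
steps_in_roi <- function(track, roi_mask, pixel_size_um) {
  n <- length(track$frames)
  mid_a <- (track$axial_um[-n] + track$axial_um[-1]) / 2
  mid_l <- (track$lateral_um[-n] + track$lateral_um[-1]) / 2
  roi_contains(roi_mask, mid_a, mid_l, pixel_size_um)
}

#' ROI flow-velocity statistics
#'
#' Each track contributes the mean of its in-ROI step speeds; the reported
#' mean is the average over contributing tracks and the max is the largest
#' per-track mean (robust to single-step noise). With no in-ROI track the
#' result is a flagged missing value, never zero.
#'
#' @param tracks list of `mb_track`.
#' @param roi_mask binary matrix on the frame grid.
#' @param pixel_size_um frame pixel pitch, micrometres.
#' @return list `mean_mm_s`, `max_mm_s`, `n_tracks`; NA with `n_tracks = 0`
#'   when no track intersects the ROI.
#' @export
roi_velocity_stats <- function(tracks, roi_mask, pixel_size_um) {
  per_track <- vapply(tracks, function(tr) {
    ins <- steps_in_roi(tr, roi_mask, pixel_size_um)
    if (!any(ins)) NA_real_ else mean(tr$step_speed_mm_s[ins])
  }, numeric(1))
  per_track <- per_track[!is.na(per_track)]
  if (!length(per_track))
    return(list(mean_mm_s = NA_real_, max_mm_s = NA_real_, n_tracks = 0L))
  list(mean_mm_s = mean(per_track), max_mm_s = max(per_track),
       n_tracks = length(per_track))
}

#' Distance-metric tortuosity of a track
#'
#' Path length divided by chord (end-to-end) length; 1 for a straight
#' track, pi/2 for a semicircle. Closed loops (zero chord) are flagged NA
#' and excluded from ROI statistics by callers.
#'
#' @param track an `mb_track` (or any list with `path_um`, `chord_um`).
#' @return tortuosity >= 1, or NA for a degenerate chord.
#' @export
track_tortuosity <- function(track) {
  if (track$chord_um <= .Machine$double.eps * track$path_um) return(NA_real_)
  track$path_um / track$chord_um
}

#' ROI tortuosity statistics
#'
#' @param tracks list of `mb_track`.
#' @param roi_mask binary frame-grid ROI.
#' @param pixel_size_um frame pixel pitch.
#' @return list `mean`, `max`, `n_tracks` over in-ROI tracks with defined
#'   tortuosity.
#' @export
roi_tortuosity_stats <- function(tracks, roi_mask, pixel_size_um) {
  vals <- vapply(tracks, function(tr) {
    ins <- steps_in_roi(tr, roi_mask, pixel_size_um)
    if (!any(ins)) return(NA_real_)
    track_tortuosity(tr)
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(list(mean = NA_real_, max = NA_real_, n_tracks = 0L))
  list(mean = mean(vals), max = max(vals), n_tracks = length(vals))
}

## internal: Zhang-Suen thinning of a logical matrix to a 1-px skeleton
zhang_suen_skeleton <- function(mask) {
  img <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  img[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask > 0)
  nbrs <- function(r, c) c(img[r - 1L, c], img[r - 1L, c + 1L], img[r, c + 1L],
                           img[r + 1L, c + 1L], img[r + 1L, c], img[r + 1L, c - 1L],
                           img[r, c - 1L], img[r - 1L, c - 1L])
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      idx <- which(img == 1L, arr.ind = TRUE)
      kill <- logical(nrow(idx))
      for (k in seq_len(nrow(idx))) {
        r <- idx[k, 1]; c <- idx[k, 2]
        p <- nbrs(r, c)           # P2..P9 clockwise from north
        B <- sum(p)
        if (B < 2L || B > 6L) next
        A <- sum(p == 0L & c(p[-1], p[1]) == 1L)
        if (A != 1L) next
        if (pass == 1L) {
          if (p[1] * p[3] * p[5] != 0L || p[3] * p[5] * p[7] != 0L) next
        } else {
          if (p[1] * p[3] * p[7] != 0L || p[1] * p[5] * p[7] != 0L) next
        }
        kill[k] <- TRUE
      }
      if (any(kill)) {
        img[idx[kill, , drop = FALSE]] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] > 0L
}

## internal: binarize an SR map for morphometry - positive bins after one
## morphological opening (removes isolated single-localization bins)
binarize_sr_map <- function(map, opening_brush = 3L) {
  b <- (map$counts > 0) * 1
  if (opening_brush > 1L)
    b <- EBImage::opening(b, EBImage::makeBrush(opening_brush, "box"))
  b > 0
}

#' Vessel diameters from a super-resolution map
#'
#' The SR map is binarized (counts > 0 after a single morphological
#' opening), skeletonized by Zhang-Suen thinning, and the local diameter at
#' each skeleton bin is twice the Euclidean distance-transform value scaled
#' by the grid spacing. Mean and maximum over skeleton bins are reported;
#' the discretization bias of the estimate is at most one SR bin.
#'
#' @param map an `sr_map`.
#' @param roi_mask optional binary frame-grid ROI (resampled to the SR grid).
#' @param pixel_size_um frame pixel pitch (needed only with `roi_mask`).
#' @param opening_brush box-brush side for the opening; 1 disables it.
#' @return list `mean_um`, `max_um`, `n_skeleton_px`; flagged NA when the
#'   binarized map is empty.
#' @export
vessel_diameters <- function(map, roi_mask = NULL, pixel_size_um = NULL,
                             opening_brush = 3L) {
  stopifnot(inherits(map, "sr_map"))
  b <- binarize_sr_map(map, opening_brush)
  if (!is.null(roi_mask)) {
    up <- map$upsampling_factor
    roi_sr <- roi_mask[rep(seq_len(nrow(roi_mask)), each = up),
                       rep(seq_len(ncol(roi_mask)), each = up)] > 0
    b <- b & roi_sr[seq_len(nrow(b)), seq_len(ncol(b))]
  }
  if (!any(b))
    return(list(mean_um = NA_real_, max_um = NA_real_, n_skeleton_px = 0L))
  dist <- EBImage::distmap(b * 1)
  skel <- zhang_suen_skeleton(b)
  d <- 2 * dist[skel] * map$spacing_um
  list(mean_um = mean(d), max_um = max(d), n_skeleton_px = sum(skel))
}

#' Box-counting fractal dimension
#'
#' Counts occupied boxes at dyadic box sizes and fits log N(s) against
#' log(1/s) by least squares; the slope is the fractal dimension. Rasters
#' of a line give ~1, filled regions ~2, a Sierpinski triangle log(3)/log(2).
#'
#' @param binary_map logical or 0/1 matrix.
#' @param scales box sizes in bins; default dyadic from 1 up to half the
#'   shorter map side.
#' @return list `fd`, `scales`, `counts`, `degenerate` (TRUE when all box
#'   counts are equal so the slope is undefined).
#' @export
fractal_dimension <- function(binary_map, scales = NULL) {
  b <- binary_map > 0
  if (!any(b)) stop("empty binary map")
  if (is.null(scales)) {
    smax <- floor(min(dim(b)) / 2)
    scales <- 2^(0:floor(log2(smax)))
  }
  scales <- as.integer(scales)
  if (length(scales) < 2L) stop("need at least two box scales")
  occ <- which(b, arr.ind = TRUE)
  counts <- vapply(scales, function(s) {
    nrow(unique(cbind((occ[, 1] - 1L) %/% s, (occ[, 2] - 1L) %/% s)))
  }, numeric(1))
  if (length(unique(counts)) == 1L)
    return(list(fd = NA_real_, scales = scales, counts = counts,
                degenerate = TRUE))
  fit <- stats::lm(log(counts) ~ log(1 / scales))
  list(fd = unname(stats::coef(fit)[2]), scales = scales, counts = counts,
       degenerate = FALSE)
}

#' Microvascular density
#'
#' Area of unique SR bins visited by tracked microbubbles divided by the
#' ROI area, as a percentage.
#'
#' @param tracked_mask logical/0-1 matrix of SR bins visited by tracked
#'   microbubbles (e.g. `counts > 0` of a track-restricted `sr_map`, or a
#'   `velocity_map`'s `counts > 0`).
#' @param roi_mask binary ROI; either on the SR grid (same size as
#'   `tracked_mask`) or on the frame grid with `upsampling_factor` given.
#' @param upsampling_factor SR upsampling when `roi_mask` is on the frame grid.
#' @return MVD in percent.
#' @export
microvascular_density <- function(tracked_mask, roi_mask,
                                  upsampling_factor = NULL) {
  tm <- tracked_mask > 0
  if (!is.null(upsampling_factor)) {
    up <- as.integer(upsampling_factor)
    roi_mask <- roi_mask[rep(seq_len(nrow(roi_mask)), each = up),
                         rep(seq_len(ncol(roi_mask)), each = up)]
  }
  roi <- roi_mask > 0
  if (!any(roi)) stop("ROI area is zero")
  if (!all(dim(tm) == dim(roi)))
    stop("tracked mask and ROI grids do not match")
  100 * sum(tm & roi) / sum(roi)
}

#' Classify the microvascular distribution pattern
#'
#' Each localization gets a normalized radial position r in \[0, 1\],
#' defined as the squared ratio of its distance from the ROI centroid to
#' the centroid-to-boundary distance along the same ray. The squaring
#' makes r area-uniform: localizations spread uniformly over the ROI give
#' a uniform r, so a uniformly vascularized lesion reads as diffuse
#' rather than peripheral. The lesion is `peripheral` if at least `frac`
#' of localizations have r > `r_outer`, `central` if at least `frac`
#' have r < `r_inner`, otherwise `diffuse`. For non-convex or
#' multiply-connected ROIs where the ray exits and re-enters, the first
#' exit defines the boundary distance.
#'
#' @param localizations data.frame `axial_um`, `lateral_um`.
#' @param roi_mask binary frame-grid ROI.
#' @param pixel_size_um frame pixel pitch.
#' @param frac vote fraction (default 0.6).
#' @param r_outer,r_inner radial thresholds (defaults 0.6 and 0.5).
#' @return list `label` in {"central","peripheral","diffuse"}, `r` vector.
#' @export
classify_distribution <- function(localizations, roi_mask, pixel_size_um,
                                  frac = 0.6, r_outer = 0.6, r_inner = 0.5) {
  ins <- roi_contains(roi_mask, localizations$axial_um,
                      localizations$lateral_um, pixel_size_um)
  loc <- localizations[ins, , drop = FALSE]
  if (!nrow(loc)) stop("no localization inside the ROI")
  idx <- which(roi_mask > 0, arr.ind = TRUE)
  cen <- c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1) * pixel_size_um
  step <- pixel_size_um / 4
  r <- vapply(seq_len(nrow(loc)), function(k) {
    v <- c(loc$axial_um[k] - cen[1], loc$lateral_um[k] - cen[2])
    d <- sqrt(sum(v^2))
    if (d == 0) return(0)
    u <- v / d
    ## march from the centroid along the ray to the first exit from the ROI
    s <- 0
    repeat {
      s <- s + step
      p <- cen + s * u
      if (!roi_contains(roi_mask, p[1], p[2], pixel_size_um)) break
      if (s > 4 * sum(dim(roi_mask)) * pixel_size_um) break  # safety
    }
    min((d / s)^2, 1)
  }, numeric(1))
  label <- if (mean(r > r_outer) >= frac) "peripheral"
           else if (mean(r < r_inner) >= frac) "central"
           else "diffuse"
  list(label = label, r = r)
}

#' Rasterize the tracked microbubble footprint onto the SR grid
#'
#' Marks every SR bin whose centre lies within `radius_um` of any track
#' point. Using a physical radius (default half a frame pixel, the scale
#' of a localized microbubble) makes the footprint area - and hence the
#' microvascular density - approximately invariant under SR-grid
#' refinement of the same geometry.
#'
#' @param points data.frame with `axial_um`, `lateral_um` (track points or
#'   localizations).
#' @param grid_px frame grid size (rows, cols).
#' @param pixel_size_um frame pixel pitch.
#' @param upsampling_factor integer SR upsampling.
#' @param radius_um footprint radius (default pixel_size_um / 2).
#' @return logical matrix on the SR grid.
#' @export
tracked_footprint <- function(points, grid_px, pixel_size_um,
                              upsampling_factor = 10L,
                              radius_um = pixel_size_um / 2) {
  s <- pixel_size_um / upsampling_factor
  nr <- grid_px[1] * upsampling_factor
  nc <- grid_px[2] * upsampling_factor
  mask <- matrix(FALSE, nr, nc)
  if (!nrow(points)) return(mask)
  hw <- ceiling(radius_um / s)
  off <- expand.grid(dr = -hw:hw, dc = -hw:hw)
  ## offsets whose bin centre lies within the footprint radius
  off <- off[(off$dr * s)^2 + (off$dc * s)^2 <= radius_um^2, ]
  ri0 <- floor((points$axial_um + pixel_size_um / 2) / s)
  ci0 <- floor((points$lateral_um + pixel_size_um / 2) / s)
  for (k in seq_len(nrow(points))) {
    rr <- ri0[k] + off$dr; cc <- ci0[k] + off$dc
    ok <- rr >= 0 & rr < nr & cc >= 0 & cc < nc
    mask[cbind(rr[ok] + 1L, cc[ok] + 1L)] <- TRUE
  }
  mask
}

#' Classify the dominant microvascular flow direction
#'
#' Length-weighted mean of the signed axial step velocities of in-ROI
#' steps: positive (increasing depth) is flow away from the transducer,
#' negative is flow toward it. An exact zero is reported as indeterminate.
#'
#' @param tracks list of `mb_track`.
#' @param roi_mask binary frame-grid ROI.
#' @param pixel_size_um frame pixel pitch.
#' @return list `label` in {"toward","away","indeterminate"},
#'   `mean_v_axial_mm_s`.
#' @export
classify_flow_direction <- function(tracks, roi_mask, pixel_size_um) {
  num <- 0; den <- 0
  for (tr in tracks) {
    ins <- steps_in_roi(tr, roi_mask, pixel_size_um)
    if (!any(ins)) next
    w <- tr$step_um[ins]
    num <- num + sum(w * tr$step_v_axial_mm_s[ins])
    den <- den + sum(w)
  }
  if (den == 0) stop("no in-ROI track step")
  v <- num / den
  label <- if (v > 0) "away" else if (v < 0) "toward" else "indeterminate"
  list(label = label, mean_v_axial_mm_s = v)
}

#' Full quantitative + qualitative metrics record for one lesion
#'
#' Convenience wrapper assembling the per-lesion record: mean/max flow
#' velocity, mean/max tortuosity, mean/largest diameter, fractal dimension,
#' microvascular density, distribution pattern and flow direction.
#'
#' @param tracks list of `mb_track`.
#' @param map an `sr_map` accumulated from the localizations.
#' @param localizations data.frame of localizations.
#' @param roi_mask binary frame-grid ROI.
#' @param pixel_size_um frame pixel pitch.
#' @param grid_px frame grid size.
#' @return one-row data.frame of class `vascular_metrics`.
#' @export
compute_vascular_metrics <- function(tracks, map, localizations, roi_mask,
                                     pixel_size_um, grid_px = dim(roi_mask)) {
  vel <- roi_velocity_stats(tracks, roi_mask, pixel_size_um)
  tor <- roi_tortuosity_stats(tracks, roi_mask, pixel_size_um)
  ## sparse maps can vanish under the opening; fall back to the raw binarization
  brush <- if (any(binarize_sr_map(map, 3L))) 3L else 1L
  dia <- vessel_diameters(map, roi_mask, pixel_size_um, opening_brush = brush)
  fdres <- fractal_dimension(binarize_sr_map(map, brush))
  track_pts <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(axial_um = tr$axial_um, lateral_um = tr$lateral_um)))
  if (is.null(track_pts))
    track_pts <- data.frame(axial_um = numeric(0), lateral_um = numeric(0))
  fp <- tracked_footprint(track_pts, grid_px, pixel_size_um,
                          map$upsampling_factor)
  mvd <- microvascular_density(fp, roi_mask, map$upsampling_factor)
  dist <- classify_distribution(localizations, roi_mask, pixel_size_um)
  dir <- classify_flow_direction(tracks, roi_mask, pixel_size_um)
  out <- data.frame(
    mean_flow_velocity_mm_s = vel$mean_mm_s,
    max_flow_velocity_mm_s = vel$max_mm_s,
    mean_tortuosity = tor$mean,
    max_tortuosity = tor$max,
    mean_diameter_um = dia$mean_um,
    largest_diameter_um = dia$max_um,
    fractal_dimension = fdres$fd,
    microvascular_density_pct = mvd,
    mv_distribution = dist$label,
    mv_flow_direction = dir$label)
  class(out) <- c("vascular_metrics", class(out))
  out
}

#' @export
print.vascular_metrics <- function(x, ...) {
  cat("<vascular_metrics>\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
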