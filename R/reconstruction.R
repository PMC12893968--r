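#' @title Super-resolution reconstruction
#' @description SVD spatiotemporal clutter filtering on the Casorati matrix,
#'   intensity-threshold microbubble detection with area/eccentricity artifact
#'   gates, intensity-weighted centroid localization, and accumulation of the
#'   super-resolved density map.
#' @name reconstruction
NULL

#' SVD spatiotemporal clutter filter
#'
#' The stack is rearranged into a Casorati matrix (pixels as rows, frames as
#' columns) and decomposed by singular value decomposition. Slow tissue and
#' background clutter concentrates in the leading singular components; the
#' stack is rebuilt from components with index in (low_cut, high_cut], which
#' retains the fast microbubble signal.
#'
#' @param stack a `frame_stack`.
#' @param low_cut number of leading (clutter) components removed; 0 removes
#'   nothing.
#' @param high_cut last retained component; defaults to the number of frames
#'   (no noise-floor cut), or `"auto"` to place it where the singular spectrum
#'   reaches its noise plateau.
#' @return A filtered `frame_stack`; the singular values are attached as
#'   attribute `"singular_values"`.
#' @export
svd_clutter_filter <- function(stack, low_cut = 1L, high_cut = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  nf <- n_frames(stack)
  if (low_cut >= nf) stop("`low_cut` must be below the number of frames")
  if (low_cut < 0) stop("`low_cut` must be >= 0")
  d <- dim(stack$frames)
  ## Casorati: one column per frame. The right singular vectors are the
  ## eigenvectors of the frame-by-frame Gram matrix t(X) X (nf x nf), which
  ## is far cheaper than a full SVD of the pixels x frames matrix; the
  ## filter then removes the rejected subspace: X - X V_rej t(V_rej).
  X <- t(matrix(stack$frames, nrow = nf))
  eg <- eigen(crossprod(X), symmetric = TRUE)
  sv_d <- sqrt(pmax(eg$values, 0))
  if (is.null(high_cut)) high_cut <- nf
  else if (identical(high_cut, "auto")) high_cut <- noise_plateau_cut(sv_d)
  if (high_cut <= low_cut || high_cut > nf)
    stop("need low_cut < high_cut <= n_frames")
  rej <- c(seq_len(low_cut), if (high_cut < nf) seq.int(high_cut + 1L, nf))
  Xf <- if (length(rej)) {
    Vr <- eg$vectors[, rej, drop = FALSE]
    X - (X %*% Vr) %*% t(Vr)
  } else X
  out <- stack
  out$frames <- array(t(Xf), dim = d)
  attr(out, "singular_values") <- sv_d
  attr(out, "cuts") <- c(low_cut = low_cut, high_cut = high_cut)
  out
}

## internal: first index where the singular spectrum flattens into the
## noise plateau (median of the trailing half), used by high_cut = "auto"
noise_plateau_cut <- function(d) {
  n <- length(d)
  floor_level <- stats::median(d[ceiling(n / 2):n])
  k <- which(d <= 1.5 * floor_level)[1]
  if (is.na(k)) n else max(k, 2L)
}

#' Suggest the clutter rank cut from the singular spectrum
#'
#' Returns the component index just before the largest multiplicative gap in
#' the singular spectrum, i.e. the point where the steep clutter decay
#' flattens. If no consecutive ratio exceeds `gap_threshold` the spectrum is
#' considered gapless and the configured minimum is returned.
#'
#' @param singular_values non-increasing, non-negative spectrum.
#' @param gap_threshold minimum ratio d\[k\]/d\[k+1\] that counts as a gap.
#' @param min_cut fallback (and lower bound) for the cut.
#' @return Integer low_cut in \[1, n).
#' @export
suggest_rank_cut <- function(singular_values, gap_threshold = 1.5,
                             min_cut = 1L) {
  d <- as.numeric(singular_values)
  if (length(d) < 2L) stop("need at least two singular values")
  if (any(diff(d) > 1e-9 * max(d))) stop("spectrum must be non-increasing")
  if (all(d == 0)) stop("all-zero singular spectrum")
  eps <- 1e-300
  ratios <- d[-length(d)] / pmax(d[-1], eps)
  if (max(ratios) < gap_threshold) return(as.integer(min_cut))
  max(as.integer(which.max(ratios)), as.integer(min_cut))
}

## internal: 8-connected labeling of a logical mask (two-pass union-find)
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  on_px <- which(mask)          # column-major scan order over masked pixels
  for (k in on_px) {
    rr <- ((k - 1L) %% nr) + 1L
    cc <- ((k - 1L) %/% nr) + 1L
    nb <- integer(0)
    if (rr > 1L && lab[rr - 1L, cc] > 0L) nb <- c(nb, lab[rr - 1L, cc])
    if (cc > 1L) {
      if (lab[rr, cc - 1L] > 0L) nb <- c(nb, lab[rr, cc - 1L])
      if (rr > 1L && lab[rr - 1L, cc - 1L] > 0L) nb <- c(nb, lab[rr - 1L, cc - 1L])
      if (rr < nr && lab[rr + 1L, cc - 1L] > 0L) nb <- c(nb, lab[rr + 1L, cc - 1L])
    }
    if (!length(nb)) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[rr, cc] <- nxt
    } else {
      roots <- vapply(nb, find, integer(1))
      r0 <- min(roots)
      lab[rr, cc] <- r0
      for (r in roots) parent[r] <- r0
    }
  }
  if (nxt == 0L) return(lab)
  ## resolve and compact labels
  roots <- vapply(seq_len(nxt), find, integer(1))
  remap <- integer(nxt)
  remap[sort(unique(roots))] <- seq_along(unique(roots))
  idx <- lab > 0L
  lab[idx] <- remap[roots[lab[idx]]]
  lab
}

#' Detect microbubbles in a clutter-filtered frame
#'
#' Pixels above an intensity threshold are grouped into 8-connected
#' components; components are kept if their area lies in
#' \[area_min_px, area_max_px\] and their eccentricity (from the eigenvalues
#' of the intensity-weighted second-moment matrix; 0 = circle) does not
#' exceed `ecc_max`. Components touching the frame border are kept but
#' flagged.
#'
#' @param frame 2-D numeric matrix (one filtered frame).
#' @param threshold absolute intensity threshold, or `NULL` for the default
#'   rule mean + 3 sd of the frame.
#' @param area_min_px,area_max_px inclusive area gate in pixels.
#' @param ecc_max maximum eccentricity in \[0, 1).
#' @return data.frame with one row per detection: `label`, `area_px`,
#'   `peak_intensity`, `eccentricity`, `touches_border`, plus a list column
#'   `pixels` of (row, col) index matrices (1-based).
#' @export
detect_microbubbles <- function(frame, threshold = NULL,
                                area_min_px = 2L, area_max_px = 60L,
                                ecc_max = 0.9) {
  stopifnot(is.matrix(frame), area_min_px >= 1L)
  if (is.null(threshold)) threshold <- mean(frame) + 3 * stats::sd(frame)
  mask <- frame > threshold
  empty <- data.frame(label = integer(0), area_px = integer(0),
                      peak_intensity = numeric(0), eccentricity = numeric(0),
                      touches_border = logical(0))
  empty$pixels <- list()
  if (!any(mask)) return(empty)
  lab <- label_components8(mask)
  nlab <- max(lab)
  keep <- vector("list", nlab)
  for (l in seq_len(nlab)) {
    px <- which(lab == l, arr.ind = TRUE)
    area <- nrow(px)
    if (area < area_min_px || area > area_max_px) next
    w <- frame[px]
    ecc <- moment_eccentricity(px, w)
    if (ecc > ecc_max) next
    keep[[l]] <- list(
      label = l, area_px = area, peak_intensity = max(w),
      eccentricity = ecc,
      touches_border = any(px[, 1] == 1L | px[, 1] == nrow(frame) |
                           px[, 2] == 1L | px[, 2] == ncol(frame)),
      pixels = px)
  }
  keep <- keep[!vapply(keep, is.null, logical(1))]
  if (!length(keep)) return(empty)
  out <- data.frame(
    label = vapply(keep, `[[`, integer(1), "label"),
    area_px = vapply(keep, `[[`, integer(1), "area_px"),
    peak_intensity = vapply(keep, `[[`, numeric(1), "peak_intensity"),
    eccentricity = vapply(keep, `[[`, numeric(1), "eccentricity"),
    touches_border = vapply(keep, `[[`, logical(1), "touches_border"))
  out$pixels <- lapply(keep, `[[`, "pixels")
  out
}

## internal: eccentricity sqrt(1 - lambda_min/lambda_max) of the
## intensity-weighted second central moment matrix; 0 for a single pixel.
## The 1/12 terms are the intra-pixel variance of a unit pixel, which keeps
## one-pixel-wide components short of the degenerate eccentricity 1.
moment_eccentricity <- function(px, w) {
  if (nrow(px) == 1L) return(0)
  w <- w / sum(w)
  mr <- sum(w * px[, 1]); mc <- sum(w * px[, 2])
  crr <- sum(w * (px[, 1] - mr)^2) + 1 / 12
  ccc <- sum(w * (px[, 2] - mc)^2) + 1 / 12
  crc <- sum(w * (px[, 1] - mr) * (px[, 2] - mc))
  ev <- eigen(matrix(c(crr, crc, crc, ccc), 2), symmetric = TRUE,
              only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

#' Sub-pixel localization by intensity-weighted centroid
#'
#' The microbubble position is the intensity-weighted mean of the pixel
#' centre positions of its detected component, converted to micrometres
#' with the 0-based top-left-origin convention.
#'
#' @param frame 2-D numeric matrix the detection came from.
#' @param detection one row of the [detect_microbubbles()] result (or a list
#'   with a `pixels` matrix).
#' @param pixel_size_um pixel pitch, micrometres.
#' @return data.frame row: `axial_um`, `lateral_um`, `intensity` (summed).
#' @export
localize_centroid <- function(frame, detection, pixel_size_um) {
  px <- if (is.data.frame(detection)) detection$pixels[[1]] else detection$pixels
  if (is.null(px) || nrow(px) == 0L) stop("detection has an empty pixel set")
  w <- frame[px]
  tot <- sum(w)
  if (tot <= 0) stop("zero total intensity in detection")
  data.frame(axial_um = sum(w * (px[, 1] - 1)) / tot * pixel_size_um,
             lateral_um = sum(w * (px[, 2] - 1)) / tot * pixel_size_um,
             intensity = tot)
}

#' Detect and localize microbubbles across a whole stack
#'
#' Convenience wrapper running [detect_microbubbles()] and
#' [localize_centroid()] frame by frame.
#'
#' @inheritParams detect_microbubbles
#' @param stack a (typically SVD-filtered) `frame_stack`.
#' @return data.frame: `frame`, `axial_um`, `lateral_um`, `intensity`.
#' @export
localize_stack <- function(stack, threshold = NULL, area_min_px = 2L,
                           area_max_px = 60L, ecc_max = 0.9) {
  stopifnot(inherits(stack, "frame_stack"))
  out <- vector("list", n_frames(stack))
  for (f in seq_len(n_frames(stack))) {
    fr <- stack$frames[f, , ]
    det <- detect_microbubbles(fr, threshold, area_min_px, area_max_px, ecc_max)
    if (!nrow(det)) next
    locs <- do.call(rbind, lapply(seq_len(nrow(det)), function(i)
      localize_centroid(fr, det[i, ], stack$pixel_size_um)))
    locs$frame <- f
    out[[f]] <- locs
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(axial_um = numeric(0), lateral_um = numeric(0),
                      intensity = numeric(0), frame = integer(0))
  out[, c("frame", "axial_um", "lateral_um", "intensity")]
}

#' Accumulate localizations into a super-resolution density map
#'
#' Each localization increments exactly one bin of a grid upsampled by an
#' integer factor relative to the frame grid, so the bin total equals the
#' number of accumulated localizations.
#'
#' @param localizations data.frame with `axial_um`, `lateral_um`.
#' @param grid_px frame grid size (rows, cols).
#' @param pixel_size_um frame pixel pitch, micrometres.
#' @param upsampling_factor integer >= 1; the SR grid spacing is
#'   pixel_size_um / upsampling_factor.
#' @return An `sr_map`.
#' @export
accumulate_density_map <- function(localizations, grid_px, pixel_size_um,
                                   upsampling_factor = 10L) {
  stopifnot(upsampling_factor >= 1L,
            upsampling_factor == as.integer(upsampling_factor))
  nr <- grid_px[1] * upsampling_factor
  nc <- grid_px[2] * upsampling_factor
  s <- pixel_size_um / upsampling_factor
  counts <- matrix(0, nr, nc)
  if (nrow(localizations)) {
    ok <- inside_fov(localizations$axial_um, localizations$lateral_um,
                     grid_px[1], grid_px[2], pixel_size_um)
    if (!all(ok))
      stop(sum(!ok), " localization(s) outside the field of view")
    ## FOV starts half a frame pixel before the first pixel centre
    ri <- pmin(pmax(floor((localizations$axial_um + pixel_size_um / 2) / s), 0), nr - 1L)
    ci <- pmin(pmax(floor((localizations$lateral_um + pixel_size_um / 2) / s), 0), nc - 1L)
    for (k in seq_along(ri))
      counts[ri[k] + 1L, ci[k] + 1L] <- counts[ri[k] + 1L, ci[k] + 1L] + 1
  }
  sr_map(counts, s, upsampling_factor)
}
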