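#' @title Microbubble tracking
#' @description Inter-frame pairing of localizations under a search-radius
#'   and normalized-cross-correlation gate, assembly of maximal tracks, and
#'   super-resolved velocity / flow-direction maps.
#' @name tracking
NULL

## internal: zero-mean NCC at zero lag between two equally cropped patches
## centred on the rounded localization positions. Patches reaching past the
## frame border are cropped symmetrically on both patches.
patch_ncc <- function(frame_a, frame_b, pos_a_px, pos_b_px, patch_px) {
  h <- (patch_px - 1L) %/% 2L
  nr <- nrow(frame_a); nc <- ncol(frame_a)
  ra <- round(pos_a_px[1]) + 1L; ca <- round(pos_a_px[2]) + 1L
  rb <- round(pos_b_px[1]) + 1L; cb <- round(pos_b_px[2]) + 1L
  ## symmetric crop: largest half-width legal for both centres
  h <- min(h, ra - 1L, nr - ra, ca - 1L, nc - ca,
              rb - 1L, nr - rb, cb - 1L, nc - cb)
  if (h < 0L) return(NA_real_)
  pa <- frame_a[(ra - h):(ra + h), (ca - h):(ca + h)]
  pb <- frame_b[(rb - h):(rb + h), (cb - h):(cb + h)]
  pa <- pa - mean(pa); pb <- pb - mean(pb)
  den <- sqrt(sum(pa^2) * sum(pb^2))
  if (den == 0) return(NA_real_)
  sum(pa * pb) / den
}

#' Pair microbubble localizations across consecutive frames
#'
#' For each localization in frame F, candidate matches in frame F+1 are the
#' localizations within `search_radius_um`; a candidate is accepted only if
#' the zero-mean normalized cross-correlation between image patches centred
#' on the two positions is at least `ncc_threshold`. One-to-one matching is
#' greedy in descending NCC, ties broken by smaller displacement and then by
#' lower frame-F index (deterministic).
#'
#' @param locs_f,locs_f1 data.frames of localizations (columns `axial_um`,
#'   `lateral_um`) for frames F and F+1.
#' @param frame_f,frame_f1 the corresponding (filtered) image frames.
#' @param pixel_size_um pixel pitch, micrometres.
#' @param search_radius_um circular search radius (default the published
#'   700 um window).
#' @param ncc_threshold minimum NCC (default the published 0.9).
#' @param patch_px odd NCC patch side in pixels.
#' @return data.frame of pairs: `i_f`, `i_f1` (row indices into the inputs),
#'   `d_axial_um`, `d_lateral_um`, `dist_um`, `ncc`. Unmatched indices are
#'   attached as attributes `unmatched_f`, `unmatched_f1`.
#' @export
pair_consecutive_frames <- function(locs_f, locs_f1, frame_f, frame_f1,
                                    pixel_size_um, search_radius_um = 700,
                                    ncc_threshold = 0.9, patch_px = 9L) {
  if (patch_px %% 2L != 1L) stop("`patch_px` must be odd")
  empty <- data.frame(i_f = integer(0), i_f1 = integer(0),
                      d_axial_um = numeric(0), d_lateral_um = numeric(0),
                      dist_um = numeric(0), ncc = numeric(0))
  n0 <- nrow(locs_f); n1 <- nrow(locs_f1)
  if (n0 == 0L || n1 == 0L) {
    attr(empty, "unmatched_f") <- seq_len(n0)
    attr(empty, "unmatched_f1") <- seq_len(n1)
    return(empty)
  }
  cand <- list()
  for (i in seq_len(n0)) {
    da <- locs_f1$axial_um - locs_f$axial_um[i]
    dl <- locs_f1$lateral_um - locs_f$lateral_um[i]
    dist <- sqrt(da^2 + dl^2)
    for (j in which(dist <= search_radius_um)) {
      ncc <- patch_ncc(frame_f, frame_f1,
                       c(locs_f$axial_um[i], locs_f$lateral_um[i]) / pixel_size_um,
                       c(locs_f1$axial_um[j], locs_f1$lateral_um[j]) / pixel_size_um,
                       patch_px)
      if (!is.na(ncc) && ncc >= ncc_threshold)
        cand[[length(cand) + 1L]] <- c(i, j, da[j], dl[j], dist[j], ncc)
    }
  }
  if (!length(cand)) {
    attr(empty, "unmatched_f") <- seq_len(n0)
    attr(empty, "unmatched_f1") <- seq_len(n1)
    return(empty)
  }
  cm <- do.call(rbind, cand)
  ## greedy: best NCC first; ties -> smaller displacement -> lower i_f.
  ## NCC is quantized to 1e-3 for the ordering so that the numerically
  ## identical scores of same-shaped microbubbles fall through to the
  ## displacement tie-break instead of being ranked by round-off noise.
  ord <- order(-round(cm[, 6], 3), cm[, 5], cm[, 1])
  used_f <- logical(n0); used_f1 <- logical(n1)
  sel <- logical(nrow(cm))
  for (k in ord) {
    i <- cm[k, 1]; j <- cm[k, 2]
    if (!used_f[i] && !used_f1[j]) {
      sel[k] <- TRUE; used_f[i] <- TRUE; used_f1[j] <- TRUE
    }
  }
  out <- as.data.frame(cm[sel, , drop = FALSE])
  names(out) <- c("i_f", "i_f1", "d_axial_um", "d_lateral_um", "dist_um", "ncc")
  out <- out[order(out$i_f), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched_f") <- which(!used_f)
  attr(out, "unmatched_f1") <- which(!used_f1)
  out
}

#' Assemble tracks from per-boundary pairings
#'
#' Pairs are chained into maximal runs over strictly consecutive frames;
#' because pairing is one-to-one per boundary, each localization belongs to
#' at most one track. Chains shorter than `min_track_len` localizations are
#' discarded.
#'
#' @param localizations data.frame over all frames: `frame`, `axial_um`,
#'   `lateral_um` (as from [localize_stack()]).
#' @param pairs list of pair data.frames, one per consecutive-frame boundary,
#'   named by the first frame index of the boundary (as produced by
#'   [track_stack()]); `i_f`/`i_f1` index the per-frame subsets of
#'   `localizations`.
#' @param min_track_len minimum localizations per track (default 5).
#' @param frame_rate_hz frame rate for speed conversion.
#' @return list of `mb_track` objects.
#' @export
assemble_tracks <- function(localizations, pairs, min_track_len = 5L,
                            frame_rate_hz) {
  frames <- sort(unique(localizations$frame))
  by_frame <- split(seq_len(nrow(localizations)), localizations$frame)
  ## successor map: global row index -> global row index in next frame
  succ <- rep(NA_integer_, nrow(localizations))
  for (bn in names(pairs)) {
    p <- pairs[[bn]]
    if (!nrow(p)) next
    f <- as.integer(bn)
    gi <- by_frame[[as.character(f)]][p$i_f]
    gj <- by_frame[[as.character(f + 1L)]][p$i_f1]
    if (any(duplicated(gi)) || any(duplicated(gj)) || any(!is.na(succ[gi])))
      stop("pairing is not one-to-one: localization matched twice")
    succ[gi] <- gj
  }
  has_pred <- rep(FALSE, nrow(localizations))
  has_pred[succ[!is.na(succ)]] <- TRUE
  tracks <- list()
  for (start in which(!has_pred & !is.na(succ))) {
    chain <- start
    while (!is.na(succ[chain[length(chain)]]))
      chain <- c(chain, succ[chain[length(chain)]])
    if (length(chain) < min_track_len) next
    tracks[[length(tracks) + 1L]] <- mb_track(
      localizations$frame[chain],
      localizations$axial_um[chain],
      localizations$lateral_um[chain],
      frame_rate_hz)
  }
  tracks
}

#' Per-step and mean track speed
#'
#' Step speed is the displacement in micrometres times the frame rate,
#' converted to mm/s.
#'
#' @param track an `mb_track`.
#' @param frame_rate_hz frame rate; defaults to the rate stored in the track.
#' @return list with `step_mm_s` and `mean_mm_s`.
#' @export
track_speeds <- function(track, frame_rate_hz = track$frame_rate_hz) {
  stopifnot(inherits(track, "mb_track"))
  step <- track$step_um * frame_rate_hz * 1e-3
  list(step_mm_s = step, mean_mm_s = mean(step))
}

#' Track a whole stack
#'
#' Runs [pair_consecutive_frames()] over every consecutive frame boundary of
#' a localization table and assembles tracks.
#'
#' @inheritParams pair_consecutive_frames
#' @param stack the (filtered) `frame_stack` the localizations came from.
#' @param localizations data.frame `frame`, `axial_um`, `lateral_um`.
#' @param min_track_len minimum track length in localizations.
#' @return list of `mb_track`; the per-boundary pair list is attached as
#'   attribute `"pairs"`.
#' @export
track_stack <- function(stack, localizations, search_radius_um = 700,
                        ncc_threshold = 0.9, patch_px = 9L,
                        min_track_len = 5L) {
  stopifnot(inherits(stack, "frame_stack"))
  nf <- n_frames(stack)
  by_frame <- split(localizations, factor(localizations$frame, levels = seq_len(nf)))
  pairs <- list()
  for (f in seq_len(nf - 1L)) {
    lf <- by_frame[[f]]; lf1 <- by_frame[[f + 1L]]
    if (!nrow(lf) || !nrow(lf1)) next
    pairs[[as.character(f)]] <- pair_consecutive_frames(
      lf, lf1, stack$frames[f, , ], stack$frames[f + 1L, , ],
      stack$pixel_size_um, search_radius_um, ncc_threshold, patch_px)
  }
  tracks <- assemble_tracks(localizations, pairs, min_track_len,
                            stack$frame_rate_hz)
  attr(tracks, "pairs") <- pairs
  tracks
}

#' Super-resolved velocity and flow-direction maps
#'
#' Every track step is rasterized onto the SR grid (bins sampled along the
#' step segment at half-bin spacing); a bin's mean speed is the average of
#' the step speeds passing through it and its direction value is the mean
#' signed axial velocity (positive = increasing depth = away from the
#' transducer). Bins never visited are NA, not zero.
#'
#' @param tracks list of `mb_track`.
#' @param grid_px frame grid size (rows, cols).
#' @param pixel_size_um frame pixel pitch, micrometres.
#' @param upsampling_factor integer SR upsampling.
#' @return list of class `velocity_map`: `speed_mm_s`, `v_axial_mm_s`
#'   (matrices with NA where undefined), `counts`, `spacing_um`.
#' @export
build_velocity_direction_maps <- function(tracks, grid_px, pixel_size_um,
                                          upsampling_factor = 10L) {
  s <- pixel_size_um / upsampling_factor
  nr <- grid_px[1] * upsampling_factor
  nc <- grid_px[2] * upsampling_factor
  speed_sum <- matrix(0, nr, nc); vax_sum <- matrix(0, nr, nc)
  counts <- matrix(0L, nr, nc)
  for (tr in tracks) {
    np <- length(tr$frames)
    for (k in seq_len(np - 1L)) {
      p0 <- c(tr$axial_um[k], tr$lateral_um[k])
      p1 <- c(tr$axial_um[k + 1L], tr$lateral_um[k + 1L])
      nsamp <- max(2L, ceiling(2 * sqrt(sum((p1 - p0)^2)) / s) + 1L)
      t <- seq(0, 1, length.out = nsamp)
      ri <- floor((p0[1] + t * (p1[1] - p0[1]) + pixel_size_um / 2) / s)
      ci <- floor((p0[2] + t * (p1[2] - p0[2]) + pixel_size_um / 2) / s)
      keep <- ri >= 0 & ri < nr & ci >= 0 & ci < nc
      bins <- unique(cbind(ri[keep], ci[keep])) + 1L
      idx <- bins[, 1] + (bins[, 2] - 1L) * nr
      speed_sum[idx] <- speed_sum[idx] + tr$step_speed_mm_s[k]
      vax_sum[idx] <- vax_sum[idx] + tr$step_v_axial_mm_s[k]
      counts[idx] <- counts[idx] + 1L
    }
  }
  speed <- speed_sum / counts; vax <- vax_sum / counts
  speed[counts == 0L] <- NA_real_; vax[counts == 0L] <- NA_real_
  structure(list(speed_mm_s = speed, v_axial_mm_s = vax, counts = counts,
                 spacing_um = s, upsampling_factor = as.integer(upsampling_factor)),
            class = "velocity_map")
}

#' @export
print.velocity_map <- function(x, ...) {
  def <- x$counts > 0L
  cat(sprintf("<velocity_map> %d x %d bins at %.3g um; %d defined, mean speed %.3g mm/s\n",
              nrow(x$counts), ncol(x$counts), x$spacing_um, sum(def),
              mean(x$speed_mm_s[def])))
  invisible(x)
}
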