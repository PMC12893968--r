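#' @title Core containers
#' @description Lightweight S3 containers shared across the pipeline:
#'   `frame_stack` (3-D intensity sequence with acquisition metadata),
#'   `sr_map` (super-resolved accumulation grid) and `mb_track`
#'   (ordered sub-pixel microbubble positions).
#' @name containers
NULL

#' Construct a frame stack
#'
#' A frame stack is the raw input to super-resolution reconstruction: a
#' sequence of 2-D intensity frames plus the two pieces of metadata every
#' downstream stage needs, the frame rate and the pixel size.
#'
#' Coordinate convention: axial position increases with the row index
#' (away from the transducer), lateral with the column index. The origin
#' sits at the centre of the top-left pixel, so pixel (row, col) using
#' 0-based indices has its centre at (row, col) * pixel_size_um.
#'
#' @param frames 3-D numeric array indexed (frame, axial row, lateral column).
#' @param frame_rate_hz acquisition frame rate in Hz (> 0).
#' @param pixel_size_um pixel pitch in micrometres (> 0).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate_hz, pixel_size_um) {
  if (length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array (frame, row, col)")
  if (dim(frames)[1] < 2L) stop("a frame stack needs at least 2 frames")
  if (!all(is.finite(frames))) stop("frame intensities must be finite")
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop("`frame_rate_hz` must be positive")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be positive")
  structure(list(frames = frames,
                 frame_rate_hz = as.numeric(frame_rate_hz),
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px, %.4g Hz, %.4g um/px\n",
              d[1], d[2], d[3], x$frame_rate_hz, x$pixel_size_um))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[1]

#' Construct a super-resolution map
#'
#' @param counts 2-D numeric matrix of localization counts (or summed
#'   intensity) on the upsampled grid.
#' @param spacing_um grid spacing in micrometres.
#' @param upsampling_factor integer upsampling relative to the frame grid.
#' @return An object of class `sr_map`.
#' @export
sr_map <- function(counts, spacing_um, upsampling_factor) {
  stopifnot(is.matrix(counts), all(counts >= 0), spacing_um > 0)
  structure(list(counts = counts, spacing_um = spacing_um,
                 upsampling_factor = as.integer(upsampling_factor)),
            class = "sr_map")
}

#' @export
print.sr_map <- function(x, ...) {
  cat(sprintf("<sr_map> %d x %d bins at %.3g um (x%d), %g localizations\n",
              nrow(x$counts), ncol(x$counts), x$spacing_um,
              x$upsampling_factor, sum(x$counts)))
  invisible(x)
}

#' @export
plot.sr_map <- function(x, log1p_scale = TRUE, ...) {
  z <- if (log1p_scale) log1p(x$counts) else x$counts
  graphics::image(t(z)[, nrow(z):1], col = grDevices::hcl.colors(64, "inferno"),
                  axes = FALSE, asp = nrow(z) / ncol(z), ...)
  invisible(x)
}

#' Construct a microbubble track
#'
#' An ordered run of sub-pixel localizations over strictly consecutive
#' frames, the carrier of all velocity and tortuosity metrics.
#'
#' @param frames integer vector of consecutive frame indices.
#' @param axial_um,lateral_um numeric positions in micrometres.
#' @param frame_rate_hz frame rate used to convert steps to speeds.
#' @return Object of class `mb_track` with per-step speeds (mm/s), path
#'   length and chord length (um) precomputed.
#' @export
mb_track <- function(frames, axial_um, lateral_um, frame_rate_hz) {
  stopifnot(length(frames) >= 2L,
            length(axial_um) == length(frames),
            length(lateral_um) == length(frames))
  if (any(diff(frames) != 1L))
    stop("track frame indices must be strictly consecutive")
  da <- diff(axial_um); dl <- diff(lateral_um)
  step_um <- sqrt(da^2 + dl^2)
  structure(list(frames = as.integer(frames),
                 axial_um = axial_um, lateral_um = lateral_um,
                 step_um = step_um,
                 step_speed_mm_s = step_um * frame_rate_hz * 1e-3,
                 step_v_axial_mm_s = da * frame_rate_hz * 1e-3,
                 path_um = sum(step_um),
                 chord_um = sqrt((axial_um[length(axial_um)] - axial_um[1])^2 +
                                 (lateral_um[length(lateral_um)] - lateral_um[1])^2),
                 frame_rate_hz = frame_rate_hz),
            class = "mb_track")
}

#' @export
print.mb_track <- function(x, ...) {
  cat(sprintf("<mb_track> %d points (frames %d-%d), mean speed %.3g mm/s\n",
              length(x$frames), x$frames[1], x$frames[length(x$frames)],
              mean(x$step_speed_mm_s)))
  invisible(x)
}

#' @export
length.mb_track <- function(x) length(x$frames)

## internal: positions (um) -> 0-based fractional pixel index
um_to_px <- function(pos_um, pixel_size_um) pos_um / pixel_size_um

## internal: is position inside the field of view spanned by an nr x nc grid?
## FOV extends half a pixel beyond the outer pixel centres.
inside_fov <- function(axial_um, lateral_um, nr, nc, pixel_size_um) {
  r <- axial_um / pixel_size_um; c <- lateral_um / pixel_size_um
  r >= -0.5 & r <= nr - 0.5 & c >= -0.5 & c <= nc - 0.5
}
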