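# Scene rendering and foveated sampling.
#
# Frames are H x W intensity grids in [0, 1] (row-major over y then x, with
# pixel centres at ((j - 0.5)/W, (i - 0.5)/H)). Three blobs: a large and a
# small object and a hand whose local pattern encodes the visible aperture
# class (POW: two wide lobes; PRE: two narrow lobes; FIST: one compact blob).

# Pixel-centre coordinate vectors for an S x S grid.
#' @keywords internal
pixel_axes <- function(S) (seq_len(S) - 0.5) / S

#' @keywords internal
add_blob <- function(img, center, sd, amp) {
  S <- nrow(img)
  ax <- pixel_axes(S)
  gx <- exp(-(ax - center[1])^2 / (2 * sd^2))
  gy <- exp(-(ax - center[2])^2 / (2 * sd^2))
  img + amp * outer(gy, gx)
}

#' @keywords internal
hand_pattern_centers <- function(hand_pos, aperture_class) {
  switch(aperture_class,
    POW  = list(offsets = c(-0.030, 0.030), sd = 0.016, amp = 0.55),
    PRE  = list(offsets = c(-0.012, 0.012), sd = 0.010, amp = 0.55),
    FIST = list(offsets = 0,               sd = 0.018, amp = 0.80)
  )
}

#' Render one frame of the action movie
#'
#' @param traj A `kin_trajectory`.
#' @param frame_idx Frame number in 1..6.
#' @param layout The `scene_layout` the trajectory was generated on.
#' @param cfg Configuration list.
#' @return A `scene_frame`: list with `image` (H x W matrix in \[0, 1\]),
#'   `hand_pos`, `aperture_class`, `frame_idx`.
#' @export
render_frame <- function(traj, frame_idx, layout, cfg = default_config()) {
  stopifnot(inherits(traj, "kin_trajectory"), inherits(layout, "scene_layout"))
  n <- nrow(traj$pos)
  if (!(frame_idx %in% seq_len(n))) {
    stop("frame_idx out of range 1..", n, call. = FALSE)
  }
  S <- cfg$full_res
  img <- matrix(0, S, S)
  img <- add_blob(img, layout$big_pos,   sd = 0.035, amp = 0.90)
  img <- add_blob(img, layout$small_pos, sd = 0.016, amp = 0.90)
  hp <- traj$pos[frame_idx, ]
  cls <- traj$aperture_class[frame_idx]
  if (is.na(cls)) cls <- "FIST"
  pat <- hand_pattern_centers(hp, cls)
  for (off in pat$offsets) {
    img <- add_blob(img, hp + c(off, 0), sd = pat$sd, amp = pat$amp)
  }
  img[] <- pmin(img, 1)
  structure(list(image = img, hand_pos = hp, aperture_class = cls,
                 frame_idx = as.integer(frame_idx)),
            class = "scene_frame")
}

#' Sample the visual field through a Gaussian foveal window
#'
#' Returns the frame intensities weighted by a Gaussian window centred on
#' the gaze; the window weights are normalized to integrate to 1 over the
#' grid, so the sum of the returned vector is the window-weighted local
#' mean intensity contribution per pixel.
#'
#' @param frame A `scene_frame`.
#' @param gaze_center 2D point in the unit square; points outside are
#'   clipped with a warning.
#' @param window_sd Window standard deviation (fraction of image size).
#' @return Numeric vector of length `H * W` (row-major by y), with the
#'   normalized window weights attached as attribute `"weights"`.
#' @export
sample_foveal_patch <- function(frame, gaze_center,
                                window_sd = default_config()$window_sd) {
  stopifnot(inherits(frame, "scene_frame"))
  if (any(gaze_center < 0 | gaze_center > 1)) {
    warning("gaze_center outside unit square; clipping", call. = FALSE)
    gaze_center <- pmin(pmax(gaze_center, 0), 1)
  }
  S <- nrow(frame$image)
  ax <- pixel_axes(S)
  gx <- exp(-(ax - gaze_center[1])^2 / (2 * window_sd^2))
  gy <- exp(-(ax - gaze_center[2])^2 / (2 * window_sd^2))
  w <- outer(gy, gx)
  w <- w / sum(w)
  out <- as.vector(frame$image * w)
  attr(out, "weights") <- as.vector(w)
  out
}
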