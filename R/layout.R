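#' Build one of the four counterbalanced target layouts
#'
#' Each layout places a big and a small object left/right of the scene and a
#' hand rest position below them, in normalized image coordinates
#' (origin top-left, x rightward, y downward, unit square). The side hosting
#' the big object is counterbalanced: layouts 1 and 4 put it left, layouts
#' 2 and 3 put it right, so that across layouts the side approached early in
#' a reach carries no information about the target's identity. The seed
#' applies a small reproducible jitter to the object positions.
#'
#' @param layout_id Integer in 1..4.
#' @param seed Integer seed for the position jitter.
#' @return An object of class `scene_layout` with fields `big_pos`,
#'   `small_pos`, `start_pos`, `via_pos`, `layout_id`, `seed`.
#' @export
#' @examples
#' make_layout(1, seed = 0)$big_pos[1] < 0.5  # big object on the left
make_layout <- function(layout_id, seed = 0L) {
  if (!is.numeric(layout_id) || length(layout_id) != 1L ||
      !(layout_id %in% 1:4)) {
    stop("layout_id must be one of 1, 2, 3, 4", call. = FALSE)
  }
  layout_id <- as.integer(layout_id)
  # Two geometries (object height differs), each mirrored once.
  geom <- if (layout_id %in% c(1, 2)) {
    list(left = c(0.22, 0.30), right = c(0.78, 0.30))
  } else {
    list(left = c(0.25, 0.40), right = c(0.75, 0.40))
  }
  big_left <- layout_id %in% c(1, 4)
  rng <- with_seed(derive_seed(seed, "layout", layout_id),
                   matrix(stats::rnorm(4, 0, 0.01), 2))
  left  <- pmin(pmax(geom$left  + rng[, 1], 0.05), 0.95)
  right <- pmin(pmax(geom$right + rng[, 2], 0.05), 0.95)
  big_pos   <- if (big_left) left else right
  small_pos <- if (big_left) right else left
  start_pos <- c(0.5, 0.68)
  # Common transport waypoint above the midpoint of the two objects: early
  # reach direction is shared across conditions (uninformative).
  via_pos <- c((big_pos[1] + small_pos[1]) / 2,
               (big_pos[2] + small_pos[2]) / 2 + 0.12)
  structure(list(big_pos = big_pos, small_pos = small_pos,
                 start_pos = start_pos, via_pos = via_pos,
                 layout_id = layout_id, seed = as.integer(seed)),
            class = "scene_layout")
}

#' @export
print.scene_layout <- function(x, ...) {
  cat(sprintf("<scene_layout %d> big (%.2f, %.2f)  small (%.2f, %.2f)  start (%.2f, %.2f)\n",
              x$layout_id, x$big_pos[1], x$big_pos[2],
              x$small_pos[1], x$small_pos[2], x$start_pos[1], x$start_pos[2]))
  invisible(x)
}
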