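# Saccade target selection, execution and the per-epoch inference loop.

#' Select the saccade target from the coarse salience map
#'
#' Argmax over the 16 x 16 grid; ties broken by the lowest row-major
#' (row-then-column) index. An all-zero map keeps the current gaze.
#'
#' @param coarse 16 x 16 salience matrix.
#' @param current_gaze Fallback point for an all-zero map.
#' @return List with `cell` (row, col), `point` (cell centre in image
#'   coordinates) and `stayed` (logical fallback flag).
#' @export
select_target <- function(coarse, current_gaze = c(0.5, 0.5)) {
  if (any(!is.finite(coarse))) stop("salience map must be finite", call. = FALSE)
  if (all(coarse == 0)) {
    ag_log("all-zero salience map; gaze stays", level = "WARN")
    return(list(cell = NULL, point = current_gaze, stayed = TRUE))
  }
  g <- nrow(coarse)
  # row-major scan: row index varies slowest
  best <- which(t(coarse) == max(coarse))[1L]   # t() makes the scan row-major
  row <- ((best - 1L) %/% g) + 1L
  col <- ((best - 1L) %% g) + 1L
  list(cell = c(row, col),
       point = c((col - 0.5) / g, (row - 0.5) / g),
       stayed = FALSE)
}

#' Execute a saccade via the proportional reflex-arc controller
#'
#' Gaze integrates toward the target over `iterations_per_saccade`
#' iterations of `ms_per_iteration` each: a discrete proportional
#' controller suppressing the proprioceptive error `target - gaze`, so the
#' error decays geometrically with factor `(1 - gain)` per iteration. Every
#' saccade consumes the full fixed duration (16 x 12 = 192 ms).
#'
#' @param gaze_pos Current gaze (2D).
#' @param target Target point in the unit square.
#' @param k Saccade index (for onset bookkeeping).
#' @param cfg Configuration list.
#' @return List with final `gaze_pos`, `trace` (iterations x 2 matrix),
#'   and the `saccade_event` (`k`, `from_pos`, `to_pos`, `onset_ms`,
#'   `duration_ms`).
#' @export
execute_saccade <- function(gaze_pos, target, k = 1L, cfg = default_config()) {
  if (any(target < 0 | target > 1)) stop("target outside unit square", call. = FALSE)
  n_it <- cfg$iterations_per_saccade
  g <- cfg$saccade_gain
  trace <- matrix(0, n_it, 2)
  pos <- gaze_pos
  for (i in seq_len(n_it)) {
    pos <- pos + g * (target - pos)
    trace[i, ] <- pos
  }
  dur <- n_it * cfg$ms_per_iteration
  ev <- structure(list(k = as.integer(k), from_pos = gaze_pos, to_pos = pos,
                       target_kind = NA_character_,
                       onset_ms = (k - 1) * dur, duration_ms = dur,
                       excluded = FALSE),
                  class = "saccade_event")
  list(gaze_pos = pos, trace = trace, event = ev)
}

#' Classify what a saccade landed on
#'
#' `BIG`/`SMALL` within `decision_radius` of an object (objects take
#' precedence, matching the decision rule), else `HAND` within
#' `hand_radius` of the hand. The saccade lands when the next video frame
#' appears, so the hand comparison uses both the current and the upcoming
#' hand position (tracking slightly ahead of the moving hand still counts
#' as a hand fixation).
#'
#' @param point Landing point.
#' @param layout A `scene_layout`.
#' @param hand_pos Current hand position, or a matrix of candidate hand
#'   positions (rows).
#' @param cfg Configuration list.
#' @return One of `"BIG"`, `"SMALL"`, `"HAND"`, `"OTHER"`.
#' @export
classify_target <- function(point, layout, hand_pos, cfg = default_config()) {
  if (dist2(point, layout$big_pos) <= cfg$decision_radius) return("BIG")
  if (dist2(point, layout$small_pos) <= cfg$decision_radius) return("SMALL")
  hp <- matrix(hand_pos, ncol = 2)
  if (min(apply(hp, 1, function(h) dist2(point, h))) <= cfg$hand_radius) {
    return("HAND")
  }
  "OTHER"
}

#' Decision check for a saccade landing
#'
#' The trial's decision is signalled when the eye lands within
#' `decision_radius` of one of the objects; there is no probability
#' threshold. Layout separation (>= 0.2) guarantees at most one object is
#' within radius.
#'
#' @param event A `saccade_event` (uses `to_pos`).
#' @param layout A `scene_layout`.
#' @param decision_radius Radius in image units.
#' @return `"BIG"`, `"SMALL"` or `"NONE"`.
#' @export
check_decision <- function(event, layout,
                           decision_radius = default_config()$decision_radius) {
  p <- event$to_pos
  if (dist2(p, layout$big_pos) <= decision_radius) return("BIG")
  if (dist2(p, layout$small_pos) <= decision_radius) return("SMALL")
  "NONE"
}

#' Run one saccade epoch
#'
#' Per-epoch order of operations: (1) sample a foveal observation of frame
#' k at the current gaze; (2) update the shape and full posteriors with the
#' frame-k kinematic observables (frame 1 is reservoir washout: it enters
#' the histories but is not scored); (3) rebuild the salience state;
#' (4) select and execute saccade k. The first saccade of every trial is
#' forced to the initial hand position (the instructed pre-trial fixation)
#' and flagged excluded from analysis.
#'
#' @param k Epoch index (1..6).
#' @param traj The trial's `kin_trajectory`.
#' @param layout A `scene_layout`.
#' @param models Sub-models from [train_submodels()].
#' @param belief Current `belief_state`.
#' @param R_prev Previous enhancement map or 0.
#' @param gaze_pos Current gaze.
#' @param cfg Configuration list.
#' @param render Logical; render the frame and store the foveal sample sum.
#' @return List with updated `belief`, `R_prev`, `gaze_pos`, the
#'   `saccade_event` (with `target_kind` filled in), the `salience_grid`
#'   (NULL for the forced first saccade), and `decision`.
#' @export
run_epoch <- function(k, traj, layout, models, belief, R_prev, gaze_pos,
                      cfg = default_config(), render = FALSE) {
  n <- cfg$n_frames
  if (k > n) stop("epoch index exceeds number of frames", call. = FALSE)
  hand_pos <- traj$pos[k, ]

  foveal_mass <- NA_real_
  if (render) {
    fr <- render_frame(traj, k, layout, cfg)
    foveal_mass <- sum(sample_foveal_patch(fr, gaze_pos, cfg$window_sd))
  }

  if (k > cfg$washout) {
    hist_idx <- seq_len(k - 1)
    belief <- update_shape_belief(belief,
                                  traj$angles[hist_idx, , drop = FALSE],
                                  traj$angles[k, ],
                                  list(SMALL = models$shape_small,
                                       BIG = models$shape_big),
                                  beta = cfg$beta_temper)
    belief <- update_full_posterior(belief,
                                    traj$pos[hist_idx, , drop = FALSE],
                                    traj$pos[k, ],
                                    traj$angles[hist_idx, , drop = FALSE],
                                    traj$angles[k, ],
                                    models, beta = cfg$beta_temper)
  }
  belief <- advance_belief(belief)

  sal <- NULL
  if (k == 1L) {
    # forced initial fixation on the hand
    ex <- execute_saccade(gaze_pos, hand_pos, k = k, cfg = cfg)
    ex$event$excluded <- TRUE
    target_point <- hand_pos
  } else {
    sal <- build_salience(belief, models,
                          traj$pos[seq_len(k), , drop = FALSE],
                          traj$angles[seq_len(k), , drop = FALSE],
                          hand_pos, layout, R_prev, k = k, cfg = cfg)
    R_prev <- sal$R_k
    tgt <- select_target(sal$coarse, gaze_pos)
    ex <- execute_saccade(gaze_pos, tgt$point, k = k, cfg = cfg)
    target_point <- tgt$point
  }
  # Hand-directed fixations include saccades to the hand's predicted next
  # position under either hypothesis (predictive tracking), not just its
  # current location.
  hand_cands <- traj$pos[c(k, min(k + 1L, n)), , drop = FALSE]
  if (!is.null(sal)) {
    hand_cands <- rbind(hand_cands, sal$c_points[[1]], sal$c_points[[2]])
  }
  ex$event$target_kind <- classify_target(target_point, layout, hand_cands, cfg)
  decision <- if (ex$event$excluded) "NONE" else {
    check_decision(ex$event, layout, cfg$decision_radius)
  }
  list(belief = belief, R_prev = R_prev, gaze_pos = ex$gaze_pos,
       event = ex$event, salience = sal, decision = decision,
       foveal_mass = foveal_mass)
}
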