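#' Generate one synthetic reach-to-grasp trajectory
#'
#' Emulates a 6-frame dataglove + motion-capture recording. The hand path is
#' a quadratic Bezier arc from the rest position through a common transport
#' waypoint to the condition's target, traversed with a minimum-jerk time
#' profile; the tangent at movement onset points at the shared waypoint, so
#' early hand position is uninformative about the goal. Joint angles
#' interpolate from the neutral rest pose toward the grip template when
#' `preshape = TRUE` (power grasps lead the transport phase, precision grips
#' lag it), and hold the FIST template on every frame when `preshape = FALSE`.
#' Gaussian noise is added per channel and frame; an optional constant
#' actor offset models between-actor variability.
#'
#' @param grip `"POW"` (power grasp, big target) or `"PRE"` (precision grip,
#'   small target).
#' @param preshape Logical; does the hand preshape during the reach?
#' @param layout A `scene_layout`.
#' @param seed Integer seed.
#' @param noise_sd Within-trial angle noise sd in degrees; default is the
#'   grip-specific value from `cfg`.
#' @param actor_offset Optional length-16 constant offset (degrees).
#' @param actor_id Integer actor label stored in the record.
#' @param cfg Configuration list from [default_config()].
#' @return A `kin_trajectory`: list with `pos` (6 x 2 matrix), `angles`
#'   (6 x 16 matrix), `aperture_class` (per frame), `grip`, `preshape`,
#'   `layout_id`, `actor_id`, `seed`.
#' @export
generate_trajectory <- function(grip = c("POW", "PRE"), preshape = TRUE,
                                layout, seed = 1L, noise_sd = NULL,
                                actor_offset = NULL, actor_id = 0L,
                                cfg = default_config()) {
  grip <- match.arg(grip)
  stopifnot(inherits(layout, "scene_layout"))
  if (is.null(noise_sd)) {
    noise_sd <- if (grip == "POW") cfg$noise_sd_pow else cfg$noise_sd_pre
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(actor_offset)) actor_offset <- rep(0, 16)
  n <- cfg$n_frames
  target <- if (grip == "POW") layout$big_pos else layout$small_pos

  with_seed(derive_seed(seed, "traj", layout$layout_id), {
    start <- layout$start_pos + stats::rnorm(2, 0, cfg$start_jitter_sd)
    tau <- (seq_len(n) - 1) / (n - 1)
    # Transport profile: min-jerk, time-compressed for the power grasp
    # (larger target => faster reach) and stretched for the precision grip.
    speed <- if (grip == "POW") cfg$approach_speed_pow else cfg$approach_speed_pre
    s <- minjerk(tau)^speed
    # Quadratic Bezier start -> via -> target under the min-jerk profile.
    via <- layout$via_pos
    pos <- cbind((1 - s)^2 * start[1] + 2 * s * (1 - s) * via[1] + s^2 * target[1],
                 (1 - s)^2 * start[2] + 2 * s * (1 - s) * via[2] + s^2 * target[2])
    jit <- matrix(stats::rnorm(2 * n, 0, cfg$pos_noise_sd), n, 2)
    jit[1, ] <- 0; jit[n, ] <- 0        # anchor the end points
    pos <- pos + jit
    pos[] <- pmin(pmax(pos, 0), 1)

    tpl <- ag_templates[[grip]]
    if (preshape) {
      lead <- if (grip == "POW") cfg$shape_lead_pow else cfg$shape_lead_pre
      u <- s^lead
      angles <- outer(1 - u, ag_templates$NEUTRAL) + outer(u, tpl)
    } else {
      angles <- matrix(ag_templates$FIST, n, 16, byrow = TRUE)
    }
    angles <- angles + matrix(rep(actor_offset, each = n), n, 16) +
      matrix(stats::rnorm(n * 16, 0, noise_sd), n, 16)
    colnames(angles) <- ag_channel_names

    aperture_class <- if (!preshape) rep("FIST", n) else {
      apply(angles, 1, function(a) {
        p <- classify_hand_pattern(a, cfg$class_kappa)
        c("POW", "PRE", "FIST")[which.max(p)]
      })
    }
    structure(list(pos = pos, angles = angles,
                   aperture_class = aperture_class,
                   grip = grip, preshape = preshape,
                   layout_id = layout$layout_id,
                   actor_id = as.integer(actor_id),
                   seed = as.integer(seed)),
              class = "kin_trajectory")
  })
}

#' @export
print.kin_trajectory <- function(x, ...) {
  cat(sprintf("<kin_trajectory> grip=%s preshape=%s layout=%d frames=%d\n",
              x$grip, x$preshape, x$layout_id, nrow(x$pos)))
  invisible(x)
}

#' Generate a full training set of grasp executions
#'
#' Emulates the movement corpus the forward sub-models are learned from:
#' `n_actors` actors each executing `n_moves_per_actor` power grasps to the
#' big object and the same number of precision grips to the small object
#' (all with preshape -- they are real grasps). Actor-level systematic angle
#' offsets model between-actor variability. Layouts rotate evenly over the
#' four counterbalanced arrangements.
#'
#' @param n_actors,n_moves_per_actor Positive counts (defaults 6 and 50).
#' @param seed Integer seed.
#' @param cfg Configuration list.
#' @return A `training_set`: list with `trajectories` (list of
#'   `kin_trajectory`), `counts` (named per-grip counts), `seed`.
#' @export
#' @examples
#' ts <- generate_training_set(1, 2, seed = 1)
#' ts$counts
generate_training_set <- function(n_actors = 6L, n_moves_per_actor = 50L,
                                  seed = 1L, cfg = default_config()) {
  if (n_actors < 1 || n_moves_per_actor < 1) {
    stop("n_actors and n_moves_per_actor must be positive", call. = FALSE)
  }
  offsets <- with_seed(derive_seed(seed, "actors"),
                       matrix(stats::rnorm(n_actors * 16, 0, cfg$actor_sd),
                              n_actors, 16))
  trajs <- list()
  idx <- 0L
  for (grip in c("POW", "PRE")) {
    for (a in seq_len(n_actors)) {
      for (m in seq_len(n_moves_per_actor)) {
        idx <- idx + 1L
        lay <- make_layout(1L + (idx %% 4L), seed = seed)
        trajs[[idx]] <- generate_trajectory(
          grip = grip, preshape = TRUE, layout = lay,
          seed = derive_seed(seed, paste0("move-", grip, "-", a), m),
          actor_offset = offsets[a, ], actor_id = a, cfg = cfg)
      }
    }
  }
  grips <- vapply(trajs, `[[`, character(1), "grip")
  structure(list(trajectories = trajs,
                 counts = c(POW = sum(grips == "POW"), PRE = sum(grips == "PRE")),
                 seed = as.integer(seed)),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> POW=%d PRE=%d trajectories\n",
              x$counts["POW"], x$counts["PRE"]))
  invisible(x)
}

#' Write a training set to CSV (one row per frame)
#'
#' Columns: trial_id, actor_id, grip, frame, x, y and the 16 angle channels.
#'
#' @param ts A `training_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_training_csv <- function(ts, path) {
  stopifnot(inherits(ts, "training_set"))
  rows <- lapply(seq_along(ts$trajectories), function(i) {
    tr <- ts$trajectories[[i]]
    data.frame(trial_id = i, actor_id = tr$actor_id, grip = tr$grip,
               frame = seq_len(nrow(tr$pos)),
               x = tr$pos[, 1], y = tr$pos[, 2], tr$angles,
               check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a training set back from CSV
#'
#' @param path CSV written by [write_training_csv()].
#' @return A `training_set` (layout/seed metadata not round-tripped).
#' @export
read_training_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  trajs <- lapply(split(df, df$trial_id), function(d) {
    d <- d[order(d$frame), ]
    ang <- as.matrix(d[, ag_channel_names])
    structure(list(pos = as.matrix(d[, c("x", "y")]),
                   angles = ang,
                   aperture_class = rep(NA_character_, nrow(d)),
                   grip = d$grip[1], preshape = TRUE,
                   layout_id = NA_integer_, actor_id = d$actor_id[1],
                   seed = NA_integer_),
              class = "kin_trajectory")
  })
  grips <- vapply(trajs, `[[`, character(1), "grip")
  structure(list(trajectories = unname(trajs),
                 counts = c(POW = sum(grips == "POW"), PRE = sum(grips == "PRE")),
                 seed = NA_integer_),
            class = "training_set")
}
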