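# The 2 x 2 (preshape x target) action-observation experiment.

ag_conditions <- c("no-shape-big", "no-shape-small",
                   "pre-shape-big", "pre-shape-small")

#' @keywords internal
parse_condition <- function(condition) {
  if (!condition %in% ag_conditions) {
    stop("condition must be one of: ", paste(ag_conditions, collapse = ", "),
         call. = FALSE)
  }
  list(preshape = grepl("^pre-shape", condition),
       grip = if (grepl("big$", condition)) "POW" else "PRE",
       target = if (grepl("big$", condition)) "BIG" else "SMALL")
}

#' Run a single observation trial
#'
#' Generates the stimulus trajectory for the condition, then runs the
#' observer: per epoch the beliefs are updated from the frame's kinematic
#' observables, the salience map is rebuilt, and a saccade is executed.
#' Belief and salience updating stop once a saccade lands on one of the
#' objects (the decision). Time is counted on the epoch clock: frame k and
#' saccade k both complete at `k * 192` ms, so the signed arrival time is
#' `(decision epoch - hand landing frame) * 192` ms.
#'
#' @param condition One of `"no-shape-big"`, `"no-shape-small"`,
#'   `"pre-shape-big"`, `"pre-shape-small"`.
#' @param layout_id Layout 1..4.
#' @param seed Integer trial seed.
#' @param models Sub-models from [train_submodels()].
#' @param cfg Configuration list.
#' @param keep_maps Keep the per-epoch coarse maps (for export/plots).
#' @param render Render frames and record foveal sample mass.
#' @return A `trial_record`.
#' @export
run_trial <- function(condition, layout_id, seed, models,
                      cfg = default_config(), keep_maps = FALSE,
                      render = FALSE) {
  cond <- parse_condition(condition)
  layout <- make_layout(layout_id, seed = cfg$seed)
  traj <- generate_trajectory(cond$grip, cond$preshape, layout,
                              seed = seed, cfg = cfg)
  target_pos <- if (cond$target == "BIG") layout$big_pos else layout$small_pos

  epoch_ms <- cfg$iterations_per_saccade * cfg$ms_per_iteration
  dland <- apply(traj$pos, 1, function(p) dist2(p, target_pos))
  hand_land_frame <- which(dland <= cfg$decision_radius)[1]
  hand_land_ms <- if (is.na(hand_land_frame)) NA_real_ else
    hand_land_frame * epoch_ms

  belief <- init_belief(cfg$prior_big, mode = cfg$prior_mode,
                        seed = derive_seed(seed, "prior-draw"), cfg = cfg)
  R_prev <- 0
  gaze <- c(0.5, 0.5)
  events <- list()
  beliefs <- matrix(NA_real_, cfg$n_frames, 5,
                    dimnames = list(NULL, c("w1", "w2", "w3", "w4", "entropy")))
  maps <- if (keep_maps) vector("list", cfg$n_frames) else NULL
  decision <- "NONE"; decision_epoch <- NA_integer_

  for (k in seq_len(cfg$n_frames)) {
    step <- run_epoch(k, traj, layout, models, belief, R_prev, gaze,
                      cfg = cfg, render = render)
    belief <- step$belief; R_prev <- step$R_prev; gaze <- step$gaze_pos
    events[[k]] <- step$event
    beliefs[k, ] <- c(belief_weights(belief), belief$entropy_full)
    if (keep_maps && !is.null(step$salience)) maps[[k]] <- step$salience$coarse
    if (step$decision != "NONE") {
      decision <- step$decision; decision_epoch <- k
      break   # belief and salience updating terminate with the decision
    }
  }
  eye_land_ms <- if (decision == "NONE") NA_real_ else decision_epoch * epoch_ms
  arrival <- if (decision == "NONE" || is.na(hand_land_ms)) NA_real_ else
    eye_land_ms - hand_land_ms

  structure(list(condition = condition, layout_id = as.integer(layout_id),
                 seed = as.integer(seed), events = events, beliefs = beliefs,
                 decision = decision, decision_epoch = decision_epoch,
                 correct = if (decision == "NONE") NA else
                   decision == cond$target,
                 hand_land_ms = hand_land_ms, eye_land_ms = eye_land_ms,
                 arrival_time_ms = arrival, maps = maps,
                 true_target = cond$target),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record %s layout %d> decision %s (epoch %s), arrival %s ms\n",
              x$condition, x$layout_id, x$decision,
              ifelse(is.na(x$decision_epoch), "-", x$decision_epoch),
              ifelse(is.na(x$arrival_time_ms), "-", x$arrival_time_ms)))
  invisible(x)
}

#' Signed arrival time of a trial
#'
#' Eye landing time minus hand landing time; negative when the eye reaches
#' the target object before the hand (anticipatory gaze). `NA` for
#' undecided trials, which are excluded from summaries.
#'
#' @param record A `trial_record`.
#' @return Signed milliseconds, or `NA` if no decision occurred.
#' @export
arrival_time <- function(record) {
  stopifnot(inherits(record, "trial_record"))
  if (record$decision == "NONE") return(NA_real_)
  record$arrival_time_ms
}

#' Summarize a set of trial records from one condition
#'
#' @param records List of `trial_record`s.
#' @return A one-row data frame: condition, n (decided), n_none, mean and
#'   sd of arrival time, fraction of anticipatory (negative) arrivals, and
#'   accuracy (decision matches the true target).
#' @export
summarize_trials <- function(records) {
  if (length(records) == 0) stop("no records to summarize", call. = FALSE)
  at <- vapply(records, arrival_time, numeric(1))
  dec <- vapply(records, `[[`, character(1), "decision")
  ok <- !is.na(at)
  correct <- vapply(records[ok], `[[`, logical(1), "correct")
  data.frame(condition = records[[1]]$condition,
             n = sum(ok), n_none = sum(!ok),
             mean_arrival_ms = if (any(ok)) mean(at[ok]) else NA_real_,
             sd_arrival_ms = if (sum(ok) > 1) stats::sd(at[ok]) else NA_real_,
             frac_anticipatory = if (any(ok)) mean(at[ok] < 0) else NA_real_,
             accuracy = if (any(ok)) mean(correct) else NA_real_,
             degenerate = !any(ok))
}

#' Run the full 2 x 2 experiment
#'
#' Trains the four sub-models (unless supplied), runs `n_per_condition`
#' trials per condition with layouts rotated evenly and per-trial seeds
#' fanned out from `seed_base`, and returns per-condition summaries plus
#' the planned contrasts (Welch two-sample tests on arrival times:
#' pre-shape vs no-shape within each grip, and big vs small within each
#' shape condition).
#'
#' @param n_per_condition Trials per condition.
#' @param seed_base Master seed.
#' @param cfg Configuration list.
#' @param models Optional pre-trained sub-models.
#' @param training Optional pre-generated `training_set`.
#' @return An `ag_experiment`: list with `records` (named by condition),
#'   `summary` (4-row data frame), `contrasts` (data frame), `cfg`.
#' @export
run_experiment <- function(n_per_condition = 50L, seed_base = 1L,
                           cfg = default_config(), models = NULL,
                           training = NULL) {
  stopifnot(n_per_condition >= 1)
  cfg <- validate_config(cfg)
  if (is.null(models)) {
    if (is.null(training)) {
      training <- generate_training_set(cfg$n_actors, cfg$n_moves_per_actor,
                                        seed = derive_seed(seed_base, "training"),
                                        cfg = cfg)
    }
    models <- train_submodels(training, cfg)
  }
  records <- list()
  for (cond in ag_conditions) {
    recs <- vector("list", n_per_condition)
    for (i in seq_len(n_per_condition)) {
      recs[[i]] <- run_trial(cond, layout_id = 1L + ((i - 1L) %% 4L),
                             seed = derive_seed(seed_base, cond, i),
                             models = models, cfg = cfg)
    }
    records[[cond]] <- recs
  }
  summary <- do.call(rbind, lapply(records, summarize_trials))
  rownames(summary) <- NULL

  at <- lapply(records, function(rs) {
    v <- vapply(rs, arrival_time, numeric(1)); v[!is.na(v)]
  })
  welch <- function(a, b) {
    if (length(at[[a]]) < 2 || length(at[[b]]) < 2 ||
        (stats::sd(at[[a]]) == 0 && stats::sd(at[[b]]) == 0)) {
      return(data.frame(contrast = paste(a, "vs", b),
                        mean_diff_ms = mean(at[[a]]) - mean(at[[b]]),
                        p_value = NA_real_))
    }
    tt <- stats::t.test(at[[a]], at[[b]])
    data.frame(contrast = paste(a, "vs", b),
               mean_diff_ms = unname(diff(rev(tt$estimate))),
               p_value = tt$p.value)
  }
  contrasts <- rbind(
    welch("pre-shape-big", "no-shape-big"),
    welch("pre-shape-small", "no-shape-small"),
    welch("pre-shape-big", "pre-shape-small"),
    welch("no-shape-big", "no-shape-small"))

  structure(list(records = records, summary = summary, contrasts = contrasts,
                 cfg = cfg, models = models, n_per_condition = n_per_condition,
                 seed_base = seed_base),
            class = "ag_experiment")
}

#' @export
print.ag_experiment <- function(x, ...) {
  cat("<activegaze experiment>", x$n_per_condition, "trials/condition\n\n")
  print(x$summary, row.names = FALSE)
  cat("\nContrasts (Welch):\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Write experiment outputs to CSV
#'
#' Writes `summary.csv`, `contrasts.csv` and `trials.csv` (one row per
#' trial with decision, timings and final beliefs) into `dir`.
#'
#' @param exp An `ag_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_csv <- function(exp, dir) {
  stopifnot(inherits(exp, "ag_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(exp$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(exp$contrasts, file.path(dir, "contrasts.csv"),
                   row.names = FALSE)
  rows <- lapply(unlist(exp$records, recursive = FALSE), function(r) {
    nb <- sum(!is.na(r$beliefs[, 1]))
    data.frame(condition = r$condition, layout_id = r$layout_id,
               seed = r$seed, decision = r$decision,
               decision_epoch = r$decision_epoch %||% NA_integer_,
               correct = r$correct,
               hand_land_ms = r$hand_land_ms, eye_land_ms = r$eye_land_ms,
               arrival_time_ms = r$arrival_time_ms,
               w4_final = r$beliefs[nb, "w4"],
               entropy_final = r$beliefs[nb, "entropy"])
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "trials.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Bar plot of mean arrival times by condition
#'
#' @param exp An `ag_experiment`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot_arrival_times <- function(exp, ...) {
  s <- exp$summary
  graphics::barplot(s$mean_arrival_ms, names.arg = s$condition,
                    ylab = "mean arrival time (ms)",
                    main = "Eye vs hand arrival by condition",
                    las = 2, ...)
}
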