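# Sequential Bayesian hypothesis testing over the two goal hypotheses.
#
# Two posteriors are tracked in log space: the shape posterior
# (w1, w2) = p(G = SMALL | hShape(1:t)), p(G = BIG | hShape(1:t)) driven by
# the preshape sub-models alone, and the full posterior
# (w3, w4) = p(G | OBS(1:t)) driven by position and shape jointly. The four
# weights parameterize the salience map.

#' Initialize the belief state
#'
#' @param prior_big Prior probability of the BIG hypothesis, in (0, 1).
#' @param mode `"uniform"` uses `prior_big` as given; `"biased"` draws the
#'   prior from a Gaussian centred on .57 with variance .01 (sd .1), clipped
#'   to (0.01, 0.99) -- a small perceptual default toward the big object.
#' @param seed Seed for the biased draw.
#' @param cfg Configuration list (supplies `sigma_obj_min`/`max`).
#' @return A `belief_state` with fields `log_shape` (log w1, w2),
#'   `log_full` (log w3, w4), `t`, `entropy_full`, `sigma_obj`.
#' @export
#' @examples
#' b <- init_belief(0.5)
#' belief_weights(b)  # w1..w4 all 0.5
init_belief <- function(prior_big = 0.5, mode = c("uniform", "biased"),
                        seed = 1L, cfg = default_config()) {
  mode <- match.arg(mode)
  if (mode == "biased") {
    prior_big <- with_seed(derive_seed(seed, "prior"),
                           stats::rnorm(1, 0.57, sqrt(0.01)))
    prior_big <- min(max(prior_big, 0.01), 0.99)
  }
  if (prior_big <= 0 || prior_big >= 1) {
    stop("prior_big must lie strictly inside (0, 1)", call. = FALSE)
  }
  lp <- log(c(SMALL = 1 - prior_big, BIG = prior_big))
  b <- structure(list(log_shape = lp, log_full = lp, t = 0L,
                      entropy_full = NA_real_, sigma_obj = NA_real_,
                      cfg_sigma = c(cfg$sigma_obj_min, cfg$sigma_obj_max)),
                 class = "belief_state")
  refresh_belief(b)
}

# Recompute entropy and the object-map dispersion from the full posterior.
#' @keywords internal
refresh_belief <- function(belief) {
  w <- exp(belief$log_full - logsumexp(belief$log_full))
  belief$entropy_full <- binary_entropy(w[1])
  s <- belief$cfg_sigma
  belief$sigma_obj <- s[1] + (s[2] - s[1]) * belief$entropy_full
  belief
}

#' Posterior weights w1..w4
#'
#' @param belief A `belief_state`.
#' @return Named vector `(w1, w2, w3, w4)`: shape posterior then full
#'   posterior, each pair summing to one.
#' @export
belief_weights <- function(belief) {
  ws <- exp(belief$log_shape - logsumexp(belief$log_shape))
  wf <- exp(belief$log_full - logsumexp(belief$log_full))
  c(w1 = unname(ws[1]), w2 = unname(ws[2]),
    w3 = unname(wf[1]), w4 = unname(wf[2]))
}

#' Update the shape posterior with one frame of preshape evidence
#'
#' `(w1, w2) <- normalize(prior * exp(beta * loglik))` with the predictive
#' log likelihood of the observed joint angles under each SHAPE sub-model
#' given the angle history. Updates are done in log space with
#' max-subtraction. If both likelihoods are -Inf the update falls back to
#' leaving the posterior unchanged, with a warning.
#'
#' @param belief A `belief_state`.
#' @param shape_history Angle history up to and including time t (rows).
#' @param shape_obs_t The newly observed angle vector (scored frame).
#' @param shape_models List with elements `SMALL` and `BIG` (`esgp_model`s).
#' @param beta Likelihood tempering exponent.
#' @return Updated `belief_state` (call [advance_belief()] once both
#'   posteriors are updated to increment `t`).
#' @export
update_shape_belief <- function(belief, shape_history, shape_obs_t,
                                shape_models, beta = 1) {
  ll <- c(predictive_loglik(shape_models$SMALL, shape_history, shape_obs_t),
          predictive_loglik(shape_models$BIG, shape_history, shape_obs_t))
  belief$log_shape <- bayes_log_update(belief$log_shape, beta * ll)
  belief
}

#' Update the full posterior with position and shape evidence
#'
#' `(w3, w4)` accumulates the sum of the position and shape predictive log
#' likelihoods per hypothesis; entropy and the object-map dispersion
#' `sigma_obj` are recomputed.
#'
#' @param belief A `belief_state`.
#' @param pos_history,pos_obs_t Position history and new observation.
#' @param shape_history,shape_obs_t Angle history and new observation.
#' @param models List from [train_submodels()].
#' @param beta Likelihood tempering exponent.
#' @return Updated `belief_state`.
#' @export
update_full_posterior <- function(belief, pos_history, pos_obs_t,
                                  shape_history, shape_obs_t, models,
                                  beta = 1) {
  ll <- c(predictive_loglik(models$pos_small, pos_history, pos_obs_t) +
            predictive_loglik(models$shape_small, shape_history, shape_obs_t),
          predictive_loglik(models$pos_big, pos_history, pos_obs_t) +
            predictive_loglik(models$shape_big, shape_history, shape_obs_t))
  belief$log_full <- bayes_log_update(belief$log_full, beta * ll)
  refresh_belief(belief)
}

# One Bayes update in log space; max-subtraction for stability.
#' @keywords internal
bayes_log_update <- function(log_prior, loglik) {
  if (all(!is.finite(loglik))) {
    warning("both hypothesis likelihoods vanished; uniform fallback", call. = FALSE)
    return(log(c(0.5, 0.5)))
  }
  lp <- log_prior + loglik
  lp - logsumexp(lp)
}

#' Advance the belief clock by one frame
#'
#' Kept separate so the shape and full posteriors update in lockstep for
#' the same frame before `t` is incremented.
#'
#' @param belief A `belief_state`.
#' @return The belief with `t` incremented.
#' @export
advance_belief <- function(belief) {
  belief$t <- belief$t + 1L
  belief
}

#' Binary entropy of the full posterior
#'
#' @param belief A `belief_state`.
#' @return Entropy of `(w3, w4)` in bits, in \[0, 1\].
#' @export
belief_entropy <- function(belief) {
  w <- belief_weights(belief)
  binary_entropy(w["w3"])
}

#' @export
print.belief_state <- function(x, ...) {
  w <- belief_weights(x)
  cat(sprintf("<belief_state t=%d> shape (%.3f, %.3f)  full (%.3f, %.3f)  H=%.3f bits\n",
              x$t, w["w1"], w["w2"], w["w3"], w["w4"], x$entropy_full))
  invisible(x)
}
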