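# Belief-weighted salience maps.
#
# Per saccade k the map is assembled as:
#   S      - epistemic value: expected information gain about the goal
#            hypothesis from a foveal sample at each candidate fixation,
#            computed exactly over a 6-symbol discrete observation alphabet
#            {hand-POW, hand-PRE, hand-FIST, big-object, small-object,
#            background};
#   S_k    - differential salience S - min(S);
#   R_k    - component enhancement: four Gaussian bumps at the predicted
#            hand positions (c1, c2; weighted by the shape posterior w1, w2)
#            and the object positions (c3, c4; weighted by the full
#            posterior times a hand-object proximity density), plus a
#            fading memory a * R_{k-1};
#   S_bar  - S_k + R_k, renormalized to max 1, then downsampled with
#            on-off centre-surround (difference-of-Gaussians) sampling to
#            the 16 x 16 sensor grid from which the saccade target is chosen.

# Squared distance of every pixel centre to a 2D point, as an S x S matrix.
#' @keywords internal
pixel_dist2 <- function(S, point) {
  ax <- pixel_axes(S)
  outer((ax - point[2])^2, (ax - point[1])^2, `+`)
}

#' Epistemic-value (expected information gain) map
#'
#' For each candidate fixation the foveal sample is modelled as a draw from
#' the 6-symbol alphabet; emission weights are Gaussian-window overlaps
#' between the fixation point and each scene item (the hand at its
#' hypothesis-specific predicted position, both objects, plus a constant
#' background weight). The hand emits the three hand symbols according to a
#' soft classification of the hypothesis's predicted joint angles. The map
#' value is the exact mutual information (bits) between the goal hypothesis
#' (distributed as the full posterior) and the sampled symbol; it is zero
#' everywhere under a degenerate belief and never exceeds the posterior
#' entropy.
#'
#' @param belief A `belief_state`.
#' @param ctx Frame context: list with `c_small`, `c_big` (predicted hand
#'   positions per hypothesis), `cls_small`, `cls_big` (probabilities over
#'   c(POW, PRE, FIST) of the predicted hand appearance), `big_pos`,
#'   `small_pos`.
#' @param cfg Configuration list.
#' @return S x S matrix of expected information gains (bits).
#' @export
epistemic_value_map <- function(belief, ctx, cfg = default_config()) {
  S <- cfg$full_res
  w <- belief_weights(belief)
  wG <- c(w["w3"], w["w4"])
  if (min(wG) <= 0) return(matrix(0, S, S))

  two_s2 <- 2 * cfg$window_sd^2
  u_big   <- exp(-pixel_dist2(S, ctx$big_pos)   / two_s2)
  u_small <- exp(-pixel_dist2(S, ctx$small_pos) / two_s2)
  u_bg <- cfg$bg_weight

  emis <- function(c_hand, cls) {
    u_hand <- exp(-pixel_dist2(S, c_hand) / two_s2)
    tot <- u_hand + u_big + u_small + u_bg
    list(pow  = u_hand * cls[1] / tot, pre = u_hand * cls[2] / tot,
         fist = u_hand * cls[3] / tot, big = u_big / tot,
         small = u_small / tot, bg = u_bg / tot)
  }
  Ps <- emis(ctx$c_small, ctx$cls_small)
  Pb <- emis(ctx$c_big, ctx$cls_big)

  mi <- matrix(0, S, S)
  for (sym in names(Ps)) {
    pmixo <- wG[1] * Ps[[sym]] + wG[2] * Pb[[sym]]
    term <- function(p, wh) {
      out <- p * 0
      nz <- p > 0
      out[nz] <- wh * p[nz] * log2(p[nz] / pmixo[nz])
      out
    }
    mi <- mi + term(Ps[[sym]], wG[1]) + term(Pb[[sym]], wG[2])
  }
  mi[mi < 0] <- 0   # clip numerical negatives
  mi
}

#' Differential salience
#'
#' @param S_map Finite numeric matrix.
#' @return `S_map - min(S_map)` (minimum exactly zero).
#' @export
differential_salience <- function(S_map) {
  if (any(!is.finite(S_map))) stop("salience map must be finite", call. = FALSE)
  S_map - min(S_map)
}

#' Effective object-component weights
#'
#' The posterior weight of each object component is multiplied by a 2D
#' Gaussian density of the current hand position centred on that object,
#' with dispersion `sigma_obj` tied to the posterior uncertainty: the
#' nearer the hand and the more confident the belief, the more strongly
#' the corresponding object attracts gaze.
#'
#' @param belief A `belief_state` (supplies `w3`, `w4` and `sigma_obj`).
#' @param hand_pos Current 2D hand position.
#' @param layout A `scene_layout`.
#' @return Named vector `c(w3_eff, w4_eff)` (SMALL then BIG object).
#' @export
object_weights <- function(belief, hand_pos, layout) {
  w <- belief_weights(belief)
  s2 <- belief$sigma_obj^2
  dens <- function(obj) exp(-sum((hand_pos - obj)^2) / (2 * s2)) / (2 * pi * s2)
  c(w3_eff = unname(w["w3"]) * dens(layout$small_pos),
    w4_eff = unname(w["w4"]) * dens(layout$big_pos))
}

#' Component enhancement map R_k
#'
#' `R_k = sum_j w_j * G(.; c_j, rho_sd) + a * R_prev` with unit-peak
#' Gaussian bumps G centred on the four component points.
#'
#' @param c_points List/matrix of four 2D points (c1, c2 hand predictions;
#'   c3, c4 object positions).
#' @param weights Numeric length-4 weights (w1, w2, w3_eff, w4_eff).
#' @param R_prev Previous enhancement map (matrix or 0).
#' @param rho_sd Bump sd as a fraction of the image (default 1/16).
#' @param a Decay weight in \[0, 1) (default 1/2).
#' @param S Image side in pixels.
#' @return S x S non-negative matrix.
#' @export
component_enhancement <- function(c_points, weights, R_prev = 0,
                                  rho_sd = 1 / 16, a = 0.5,
                                  S = default_config()$full_res) {
  stopifnot(length(c_points) == 4, length(weights) == 4, a >= 0, a < 1,
            rho_sd > 0)
  R <- matrix(0, S, S)
  for (j in 1:4) {
    if (weights[j] == 0) next
    R <- R + weights[j] * exp(-pixel_dist2(S, c_points[[j]]) / (2 * rho_sd^2))
  }
  R + a * R_prev
}

#' Combine differential salience and enhancement
#'
#' @param S_k Differential salience map.
#' @param R_k Component enhancement map.
#' @return Elementwise sum `S_k + R_k`.
#' @export
compose_enhanced <- function(S_k, R_k) {
  if (!all(dim(S_k) == dim(R_k))) stop("map shapes differ", call. = FALSE)
  S_k + R_k
}

# Row-normalized 1D Gaussian blur matrix (truncated at the image border).
#' @keywords internal
blur_matrix <- function(S, sd_px) {
  idx <- seq_len(S)
  K <- exp(-outer(idx, idx, `-`)^2 / (2 * sd_px^2))
  K / rowSums(K)
}

#' Centre-surround downsampling to the 16 x 16 sensor grid
#'
#' On-off centre-surround sampling: a difference-of-Gaussians (centre sd =
#' half a grid cell, surround sd = twice the centre sd) is applied at full
#' resolution, rectified at zero, and block-averaged into the coarse grid.
#'
#' @param full_res Square matrix whose side is divisible by 16.
#' @param grid Coarse grid side (16).
#' @return `grid` x `grid` non-negative matrix.
#' @export
downsample_center_surround <- function(full_res, grid = 16L) {
  S <- nrow(full_res)
  if (ncol(full_res) != S || S %% grid != 0) {
    stop("full-resolution map side must be square and divisible by ", grid,
         call. = FALSE)
  }
  cell <- S / grid
  Kc <- blur_matrix(S, cell / 2)
  Ks <- blur_matrix(S, cell)
  dog <- (Kc %*% full_res %*% t(Kc)) - (Ks %*% full_res %*% t(Ks))
  dog[dog < 0] <- 0
  # block average
  agg <- matrix(0, grid, S)
  for (i in seq_len(grid)) {
    agg[i, ] <- colMeans(dog[((i - 1) * cell + 1):(i * cell), , drop = FALSE])
  }
  out <- matrix(0, grid, grid)
  for (j in seq_len(grid)) {
    out[, j] <- rowMeans(agg[, ((j - 1) * cell + 1):(j * cell), drop = FALSE])
  }
  out
}

#' Assemble the salience state for one saccade
#'
#' Runs the full pipeline: epistemic map from the current belief and
#' predictions, differential salience, component enhancement with the
#' belief-weighted c-points, composition, renormalization to max 1, and
#' centre-surround downsampling.
#'
#' @param belief A `belief_state`.
#' @param models Sub-model list from [train_submodels()].
#' @param pos_history,shape_history Observed histories (rows = frames).
#' @param hand_pos Current hand position (for the object proximity term).
#' @param layout A `scene_layout`.
#' @param R_prev Previous enhancement map or 0.
#' @param k Saccade index.
#' @param cfg Configuration list.
#' @return A `salience_grid`: list with `full_res` (the renormalized
#'   combined map), `S_map`, `S_k`, `R_k`, `coarse`, `c_points`, `weights`,
#'   `k`.
#' @export
build_salience <- function(belief, models, pos_history, shape_history,
                           hand_pos, layout, R_prev = 0, k = 1L,
                           cfg = default_config()) {
  pd_ps <- predict_next(models$pos_small, pos_history)
  pd_pb <- predict_next(models$pos_big, pos_history)
  pd_ss <- predict_next(models$shape_small, shape_history)
  pd_sb <- predict_next(models$shape_big, shape_history)

  c_small <- pmin(pmax(pd_ps$mean, 0), 1)
  c_big   <- pmin(pmax(pd_pb$mean, 0), 1)
  if (isTRUE(cfg$sample_c_points)) {
    c_small <- pmin(pmax(with_seed(derive_seed(cfg$seed, "cpt", k),
                                   stats::rnorm(2, pd_ps$mean, sqrt(pd_ps$var))), 0), 1)
    c_big <- pmin(pmax(with_seed(derive_seed(cfg$seed, "cpt2", k),
                                 stats::rnorm(2, pd_pb$mean, sqrt(pd_pb$var))), 0), 1)
  }
  ctx <- list(c_small = c_small, c_big = c_big,
              cls_small = classify_hand_pattern(pd_ss$mean, cfg$class_kappa),
              cls_big = classify_hand_pattern(pd_sb$mean, cfg$class_kappa),
              big_pos = layout$big_pos, small_pos = layout$small_pos)

  S_map <- epistemic_value_map(belief, ctx, cfg)
  S_k <- differential_salience(S_map)

  w <- belief_weights(belief)
  ow <- object_weights(belief, hand_pos, layout)
  if (isTRUE(cfg$ablate_object_components)) ow[] <- 0
  weights <- c(w["w1"], w["w2"], ow["w3_eff"], ow["w4_eff"])
  c_points <- list(c_small, c_big, layout$small_pos, layout$big_pos)
  R_k <- component_enhancement(c_points, weights, R_prev,
                               rho_sd = cfg$rho_sd, a = cfg$decay_a,
                               S = cfg$full_res)
  S_bar <- compose_enhanced(S_k, R_k)
  m <- max(S_bar)
  if (m > 0) S_bar <- S_bar / m   # renormalize; argmax invariant
  structure(list(full_res = S_bar, S_map = S_map, S_k = S_k, R_k = R_k,
                 coarse = downsample_center_surround(S_bar, cfg$coarse_grid),
                 c_points = c_points, weights = weights, k = as.integer(k)),
            class = "salience_grid")
}

#' @export
print.salience_grid <- function(x, ...) {
  cat(sprintf("<salience_grid k=%d> full %dx%d, coarse %dx%d, weights %s\n",
              x$k, nrow(x$full_res), ncol(x$full_res), nrow(x$coarse),
              ncol(x$coarse), paste(signif(x$weights, 3), collapse = " ")))
  invisible(x)
}
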