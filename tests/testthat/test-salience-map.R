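cfg <- default_config()

# independent oracle: mutual information between goal and symbol from the
# joint distribution, with emissions recomputed from first principles
mi_oracle <- function(eta, belief_w, ctx, cfg) {
  g <- exp(-((eta[1] - c(ctx$c_small[1], ctx$big_pos[1], ctx$small_pos[1]))^2 +
             (eta[2] - c(ctx$c_small[2], ctx$big_pos[2], ctx$small_pos[2]))^2) /
           (2 * cfg$window_sd^2))
  gb <- exp(-((eta[1] - c(ctx$c_big[1], ctx$big_pos[1], ctx$small_pos[1]))^2 +
              (eta[2] - c(ctx$c_big[2], ctx$big_pos[2], ctx$small_pos[2]))^2) /
            (2 * cfg$window_sd^2))
  emis <- function(u_hand, u_big, u_small, cls) {
    tot <- u_hand + u_big + u_small + cfg$bg_weight
    c(u_hand * cls / tot, u_big / tot, u_small / tot, cfg$bg_weight / tot)
  }
  Ps <- emis(g[1], g[2], g[3], ctx$cls_small)
  Pb <- emis(gb[1], gb[2], gb[3], ctx$cls_big)
  joint <- rbind(belief_w[1] * Ps, belief_w[2] * Pb)
  pg <- rowSums(joint); po <- colSums(joint)
  sum(ifelse(joint > 0, joint * log2(joint / outer(pg, po)), 0))
}

random_ctx <- function(seed) {
  set.seed(seed)
  list(c_small = runif(2, 0.1, 0.9), c_big = runif(2, 0.1, 0.9),
       cls_small = c(prop.table(runif(3))), cls_big = c(prop.table(runif(3))),
       big_pos = runif(2, 0.1, 0.9), small_pos = runif(2, 0.1, 0.9))
}

test_that("the epistemic map equals brute-force mutual information", {
  for (f in 1:20) {
    ctx <- random_ctx(f)
    w4 <- runif(1, 0.05, 0.95)
    b <- init_belief(w4, cfg = cfg)
    S <- epistemic_value_map(b, ctx, cfg)
    H <- binaryH <- -w4 * log2(w4) - (1 - w4) * log2(1 - w4)
    expect_true(all(S >= 0))
    expect_true(all(S <= H + 1e-9))
    # compare at 5 random pixels against the joint-distribution oracle
    ax <- (seq_len(cfg$full_res) - 0.5) / cfg$full_res
    set.seed(f + 100)
    for (q in 1:5) {
      i <- sample.int(cfg$full_res, 1); j <- sample.int(cfg$full_res, 1)
      expect_lt(abs(S[i, j] -
                    mi_oracle(c(ax[j], ax[i]), c(1 - w4, w4), ctx, cfg)),
                1e-9)
    }
  }
})

test_that("a degenerate belief yields a null epistemic map", {
  ctx <- random_ctx(1)
  b <- init_belief(0.5, cfg = cfg)
  b$log_full <- c(-Inf, 0)
  b <- activegaze:::refresh_belief(b)
  expect_true(all(epistemic_value_map(b, ctx, cfg) == 0))
})

test_that("a perfectly revealing hand sample is worth the full posterior
           entropy", {
  # both hypotheses place the hand at the same spot but with certain,
  # opposite patterns; objects far away
  ctx <- list(c_small = c(0.5, 0.5), c_big = c(0.5, 0.5),
              cls_small = c(0, 1, 0), cls_big = c(1, 0, 0),
              big_pos = c(0.05, 0.05), small_pos = c(0.95, 0.05))
  b <- init_belief(0.5, cfg = cfg)
  S <- epistemic_value_map(b, ctx, cfg)
  expect_gt(max(S), 0.95)                   # ~1 bit at the hand
  ij <- which(S == max(S), arr.ind = TRUE)[1, ]
  ax <- (seq_len(cfg$full_res) - 0.5) / cfg$full_res
  expect_lt(max(abs(c(ax[ij[2]], ax[ij[1]]) - c(0.5, 0.5))), 0.05)
})

test_that("differential salience shifts the minimum to zero, preserving argmax", {
  set.seed(3)
  m <- matrix(runif(64, 0.2, 1), 8)
  d <- differential_salience(m)
  expect_equal(min(d), 0)
  expect_equal(which.max(d), which.max(m))
  expect_true(all(differential_salience(matrix(0.7, 4, 4)) == 0))
  expect_error(differential_salience(matrix(c(1, NA, 1, 1), 2)), "finite")
})

test_that("component enhancement follows the geometric-decay closed form", {
  pts <- list(c(0.3, 0.3), c(0.7, 0.3), c(0.3, 0.7), c(0.7, 0.7))
  w <- c(1, 0, 0, 0)
  R1 <- component_enhancement(pts, w, 0, rho_sd = 1 / 16, a = 0.5, S = 64)
  # single unit-peak bump at c1 (peak sits on the nearest pixel centre)
  expect_gt(max(R1), 0.99)
  expect_lte(max(R1), 1)
  ij <- which(R1 == max(R1), arr.ind = TRUE)[1, ]
  expect_lt(max(abs((c(ij[2], ij[1]) - 0.5) / 64 - pts[[1]])), 1 / 64)
  # frozen components: R_k -> 2 x stationary sum; residual halves per step
  w4 <- c(0.4, 0.3, 0.2, 0.1)
  base <- component_enhancement(pts, w4, 0, a = 0.5, S = 32)
  limit <- 2 * base
  R <- 0
  res_prev <- Inf
  for (k in 1:8) {
    R <- component_enhancement(pts, w4, R, a = 0.5, S = 32)
    res <- max(abs(R - limit))
    if (k > 1) expect_equal(res / res_prev, 0.5, tolerance = 1e-6)
    res_prev <- res
  }
  # decay contraction: successive differences shrink monotonically
  expect_lt(res_prev, 0.01 * max(limit))
})

test_that("object weights grow with proximity and confidence", {
  lay <- make_layout(1, seed = 0)
  b <- init_belief(0.8, cfg = cfg)
  at_obj <- object_weights(b, lay$big_pos, lay)
  near <- object_weights(b, lay$big_pos + c(0.05, 0), lay)
  far <- object_weights(b, lay$big_pos + c(5 * b$sigma_obj, 0), lay)
  expect_gt(at_obj["w4_eff"], near["w4_eff"])
  expect_gt(near["w4_eff"], far["w4_eff"])
  expect_lt(far["w4_eff"], 1e-3 * at_obj["w4_eff"])
  # density peak value at zero distance
  expect_equal(unname(at_obj["w4_eff"]),
               0.8 / (2 * pi * b$sigma_obj^2), tolerance = 1e-9)
})

test_that("composition is an elementwise sum with shape checking", {
  A <- matrix(1:4, 2); B <- matrix(0, 2, 2)
  expect_equal(compose_enhanced(A, B), A)
  expect_equal(compose_enhanced(B, A), A)
  expect_error(compose_enhanced(A, matrix(0, 3, 3)), "shape")
  # a strong bump can relocate the argmax
  S_k <- matrix(0, 32, 32); S_k[5, 5] <- 0.4
  R_k <- component_enhancement(list(c(0.8, 0.8), c(0, 0), c(0, 0), c(0, 0)),
                               c(1, 0, 0, 0), 0, a = 0.5, S = 32)
  comb <- compose_enhanced(S_k, R_k)
  expect_false(which.max(comb) == which.max(S_k))
})

test_that("centre-surround downsampling matches a direct DoG computation", {
  set.seed(9)
  m <- matrix(0, 32, 32)
  m[10, 20] <- 1; m[25, 6] <- 0.5
  out <- downsample_center_surround(m, grid = 16L)
  expect_equal(dim(out), c(16L, 16L))        # 256 sensors
  # direct oracle: explicit truncated-Gaussian kernels, then block means
  cell <- 2
  kern <- function(sd) {
    K <- exp(-outer(1:32, 1:32, `-`)^2 / (2 * sd^2))
    K / rowSums(K)
  }
  dog <- kern(1) %*% m %*% t(kern(1)) - kern(2) %*% m %*% t(kern(2))
  dog[dog < 0] <- 0
  oracle <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    oracle[i, j] <- mean(dog[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  expect_equal(out, oracle, tolerance = 1e-12)
  # constant input cancels; point input leaves a positive centre
  expect_true(all(abs(downsample_center_surround(matrix(1, 32, 32), 16L)) < 1e-9))
  expect_gt(out[5, 10], 0)
  expect_error(downsample_center_surround(matrix(0, 30, 30)), "divisible")
})

test_that("the assembled map is a belief-weighted average, renormalized", {
  models <- small_models()
  lay <- make_layout(1, seed = 0)
  tr <- generate_trajectory("POW", TRUE, lay, seed = 21, cfg = cfg)
  b <- init_belief(0.7, cfg = cfg)
  sal <- build_salience(b, models, tr$pos[1:3, ], tr$angles[1:3, ],
                        tr$pos[3, ], lay, R_prev = 0, k = 3, cfg = cfg)
  expect_equal(max(sal$full_res), 1)
  expect_equal(dim(sal$coarse), c(16L, 16L))
  expect_true(all(sal$full_res >= 0))
  expect_equal(sal$c_points[[3]], lay$small_pos)
  expect_equal(sal$c_points[[4]], lay$big_pos)
  # renormalization leaves the argmax where S_k + R_k put it
  raw <- compose_enhanced(sal$S_k, sal$R_k)
  expect_equal(which.max(sal$full_res), which.max(raw))
})
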