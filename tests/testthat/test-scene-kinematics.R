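cfg <- default_config()

test_that("the four layouts counterbalance big-object side and are valid", {
  lays <- lapply(1:4, make_layout, seed = 0)
  big_left <- vapply(lays, function(l) l$big_pos[1] < 0.5, logical(1))
  expect_equal(sum(big_left), 2L)          # each side hosts big in 2 layouts
  expect_true(big_left[1])                  # layout 1: big left
  expect_false(big_left[2])                 # layout 2: mirrored
  for (l in lays) {
    pts <- rbind(l$big_pos, l$small_pos, l$start_pos)
    expect_true(all(pts >= 0 & pts <= 1))
    d <- as.matrix(dist(pts))
    expect_true(all(d[upper.tri(d)] >= 0.2))
  }
  expect_identical(make_layout(3, seed = 5), make_layout(3, seed = 5))
  expect_error(make_layout(5, seed = 0), "layout_id")
})

test_that("trajectories honour frame count, endpoints and channel layout", {
  lay <- make_layout(1, seed = 0)
  tr <- generate_trajectory("POW", TRUE, lay, seed = 3, cfg = cfg)
  expect_equal(nrow(tr$pos), 6L)
  expect_equal(ncol(tr$angles), 16L)        # 3 per finger + wrist
  expect_lt(activegaze:::dist2(tr$pos[1, ], lay$start_pos), 4 * cfg$start_jitter_sd)
  expect_lt(activegaze:::dist2(tr$pos[6, ], lay$big_pos), cfg$decision_radius)
  tr2 <- generate_trajectory("PRE", TRUE, lay, seed = 3, cfg = cfg)
  expect_lt(activegaze:::dist2(tr2$pos[6, ], lay$small_pos), cfg$decision_radius)
  expect_true(all(is.finite(tr$angles)))
  expect_error(generate_trajectory("POW", TRUE, lay, seed = 1, noise_sd = -1),
               "noise_sd")
})

test_that("no-shape trials hold the fist template on every frame", {
  lay <- make_layout(2, seed = 0)
  fist <- grip_template("FIST")
  for (s in 1:5) {
    tr <- generate_trajectory("POW", FALSE, lay, seed = s, noise_sd = 1,
                              cfg = cfg)
    dev <- abs(sweep(tr$angles, 2, fist))
    expect_lt(max(dev), 5)                  # all channels near FIST (1 deg noise)
    expect_true(all(tr$aperture_class == "FIST"))
  }
})

test_that("precision preshape closes the thumb-index aperture monotonically", {
  for (s in 1:20) {
    lay <- make_layout(1 + s %% 4, seed = 0)
    tr <- generate_trajectory("PRE", TRUE, lay, seed = s, noise_sd = 0,
                              cfg = cfg)
    ap <- apply(tr$angles, 1, grip_aperture)
    expect_true(all(diff(ap) < 0))
    # power grasp opens instead
    trp <- generate_trajectory("POW", TRUE, lay, seed = s, noise_sd = 0,
                               cfg = cfg)
    expect_true(all(diff(apply(trp$angles, 1, grip_aperture)) > 0))
  }
})

test_that("training sets have the designed per-grip counts and fresh noise", {
  ts <- small_training()
  expect_equal(unname(ts$counts), c(20L, 20L))   # 2 actors x 10 moves
  ts1 <- generate_training_set(1, 1, seed = 4, cfg = cfg)
  expect_equal(unname(ts1$counts), c(1L, 1L))
  ts2 <- generate_training_set(1, 1, seed = 5, cfg = cfg)
  expect_false(isTRUE(all.equal(ts1$trajectories[[1]]$angles,
                                ts2$trajectories[[1]]$angles)))
})

test_that("full-size generation yields 300 trajectories per sub-model", {
  ts <- generate_training_set(6, 50, seed = 2, cfg = cfg)
  expect_equal(unname(ts$counts["POW"]), 300L)
  expect_equal(unname(ts$counts["PRE"]), 300L)
})

test_that("training CSV round-trips per-frame kinematics", {
  ts <- generate_training_set(1, 2, seed = 9, cfg = cfg)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_training_csv(ts, path)
  back <- read_training_csv(path)
  expect_equal(unname(back$counts), unname(ts$counts))
  expect_equal(back$trajectories[[1]]$angles, ts$trajectories[[1]]$angles,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("rendered frames place three blobs and are deterministic", {
  lay <- make_layout(1, seed = 0)
  tr <- generate_trajectory("POW", TRUE, lay, seed = 1, cfg = cfg)
  fr <- render_frame(tr, 1, lay, cfg)
  expect_true(all(fr$image >= 0 & fr$image <= 1))
  # local intensity near each of the three expected centres
  peak_near <- function(p) {
    S <- nrow(fr$image)
    i <- round(p[2] * S); j <- round(p[1] * S)
    max(fr$image[pmax(1, i - 3):pmin(S, i + 3), pmax(1, j - 3):pmin(S, j + 3)])
  }
  expect_gt(peak_near(lay$big_pos), 0.5)
  expect_gt(peak_near(lay$small_pos), 0.5)
  expect_gt(peak_near(tr$pos[1, ]), 0.3)
  expect_identical(render_frame(tr, 3, lay, cfg)$image,
                   render_frame(tr, 3, lay, cfg)$image)
  expect_error(render_frame(tr, 7, lay, cfg), "frame_idx")
})

test_that("hand patterns for the two grips are template-discriminable", {
  lay <- make_layout(1, seed = 0)
  mk_frame <- function(cls, frame_idx) {
    tr <- generate_trajectory("POW", TRUE, lay, seed = 1, cfg = cfg)
    tr$aperture_class[] <- cls
    render_frame(tr, frame_idx, lay, cfg)
  }
  patch <- function(fr) {
    S <- nrow(fr$image)
    i <- round(fr$hand_pos[2] * S); j <- round(fr$hand_pos[1] * S)
    fr$image[(i - 8):(i + 8), (j - 8):(j + 8)]
  }
  # hand-centred probe patches (frame 4) vs reference patterns rendered at a
  # different scene position (frame 3): correlation must follow the pattern
  pow_ref <- patch(mk_frame("POW", 3)); pre_ref <- patch(mk_frame("PRE", 3))
  pow_probe <- patch(mk_frame("POW", 4)); pre_probe <- patch(mk_frame("PRE", 4))
  expect_gt(cor(as.vector(pow_probe), as.vector(pow_ref)),
            cor(as.vector(pow_probe), as.vector(pre_ref)))
  expect_gt(cor(as.vector(pre_probe), as.vector(pre_ref)),
            cor(as.vector(pre_probe), as.vector(pow_ref)))
})

test_that("foveal windows are normalized and locally selective", {
  lay <- make_layout(1, seed = 0)
  tr <- generate_trajectory("POW", TRUE, lay, seed = 1, cfg = cfg)
  fr <- render_frame(tr, 1, lay, cfg)
  v <- sample_foveal_patch(fr, lay$big_pos, cfg$window_sd)
  expect_equal(sum(attr(v, "weights")), 1, tolerance = 1e-9)
  v_bg <- sample_foveal_patch(fr, c(0.05, 0.95), cfg$window_sd)
  expect_gt(sum(v), 10 * sum(v_bg))          # object beats empty background
  expect_warning(sample_foveal_patch(fr, c(1.2, 0.5)), "clipping")
})

test_that("early hand position carries no information about target side", {
  sides <- logical(240); xs <- numeric(240)
  for (s in 1:240) {
    lay <- make_layout(1 + (s - 1) %% 4, seed = cfg$seed)
    g <- if (s %% 2 == 0) "POW" else "PRE"
    tr <- generate_trajectory(g, s %% 3 == 0, lay, seed = 6000 + s, cfg = cfg)
    tgt <- if (g == "POW") lay$big_pos else lay$small_pos
    sides[s] <- tgt[1] > 0.5
    xs[s] <- tr$pos[2, 1]
  }
  bins <- cut(xs, breaks = stats::quantile(xs, 0:4 / 4), include.lowest = TRUE)
  p <- table(bins, sides) / length(xs)
  mi <- sum(ifelse(p > 0, p * log2(p / outer(rowSums(p), colSums(p))), 0))
  expect_lt(mi, 0.05)
})

test_that("frame-2 joint angles reveal the grip only under preshape", {
  fit_readout_disc <- function(pre, n = 400) {
    X <- matrix(0, n, 16); y <- logical(n)
    for (s in 1:n) {
      g <- if (s %% 2 == 0) "POW" else "PRE"
      lay <- make_layout(1 + s %% 4, seed = cfg$seed)
      tr <- generate_trajectory(g, pre, lay, seed = 5000 + s, cfg = cfg)
      X[s, ] <- tr$angles[2, ]; y[s] <- g == "POW"
    }
    df <- data.frame(y = y, X)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = binomial))
    null <- stats::glm(y ~ 1, data = df, family = binomial)
    list(p = stats::pchisq(null$deviance - fit$deviance, df = 16,
                           lower.tail = FALSE),
         acc = mean((stats::fitted(fit) > 0.5) == y), n = n)
  }
  pre <- fit_readout_disc(TRUE)
  expect_lt(pre$p, 0.01)                     # above chance with preshape
  no <- fit_readout_disc(FALSE)
  ci <- no$acc + c(-1.96, 1.96) * sqrt(0.25 / no$n)
  expect_true(ci[1] <= 0.5 + 0.05)           # chance inside the 95% band
})
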