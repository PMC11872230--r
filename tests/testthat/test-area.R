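# Synchronicity merging and area-threshold evaluation.

mk_trans <- function(times, dirs, blocks, kind = "luminance", mag = 40,
                     pre = 20, post = 60) {
  data.frame(kind = kind, direction = dirs, time = times,
             anchor_time = times, span = 0, magnitude = mag,
             pre = pre, post = post, block = blocks)
}

grid_stub <- function(env, block_px = 1) {
  f <- array(0.3, c(env$height_px, env$width_px, 3))
  fh_build_grid(fh_frames(list(f, f), fps = 60), env, block_px = block_px)
}

test_that("areas transitioning within 20 ms merge; beyond 20 ms do not", {
  env <- fh_env(8, 4, px_angular_size = 0.1)
  g <- grid_stub(env)
  # two areas, leading edges one 60 fps frame apart (16.7 ms) -> one event
  tr <- mk_trans(c(0, 1 / 60), c(1, 1), blocks = c(1, 2))
  ev <- fh_merge_synchronous(tr, g, 0.020)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$area_px2, 2)
  # two frames apart (33.3 ms) -> separate events
  tr2 <- mk_trans(c(0, 2 / 60), c(1, 1), blocks = c(1, 2))
  expect_equal(nrow(fh_merge_synchronous(tr2, g, 0.020)), 2)
  # opposite directions never merge
  tr3 <- mk_trans(c(0, 0), c(1, -1), blocks = c(1, 2))
  expect_equal(nrow(fh_merge_synchronous(tr3, g, 0.020)), 2)
})

test_that("member areas are conserved and blocks never double-counted", {
  env <- fh_env(8, 4, px_angular_size = 0.1)
  g <- grid_stub(env)
  tr <- mk_trans(c(0, 0.001, 0.002), c(1, 1, 1), blocks = c(3, 4, 3))
  ev <- fh_merge_synchronous(tr, g, 0.020)
  # block 3 appears twice within the window: once in this event, and its
  # second transition seeds a second event
  expect_equal(nrow(ev), 2)
  expect_equal(ev$area_px2[1], 2)
  expect_equal(ev$area_px2[2], 1)
  expect_equal(sum(ev$n_blocks), 3)
})

test_that("the windowed 25% boundary is strict (at the limit is compliant)", {
  # window larger than the frame: it clips to the whole frame, so the
  # fraction is an exact pixel count over the frame area
  env <- fh_env(20, 20, px_angular_size = 0.25)
  g <- grid_stub(env)
  p <- fh_profile("proposed")
  blocks_at <- function(n) seq_len(n)
  ev <- fh_merge_synchronous(mk_trans(rep(0, 100), rep(1, 100),
                                      blocks_at(100)), g, 0.02)
  ev <- fh_evaluate_area(ev, g, p)
  expect_equal(ev$windowed_fraction, 0.25)
  expect_false(ev$hazardous_area)
  ev2 <- fh_merge_synchronous(mk_trans(rep(0, 101), rep(1, 101),
                                       blocks_at(101)), g, 0.02)
  ev2 <- fh_evaluate_area(ev2, g, p)
  expect_true(ev2$hazardous_area)
})

test_that("screen-fraction mode compares the summed area against 25% of the frame", {
  env <- fh_env(20, 20, px_angular_size = 0.25)
  g <- grid_stub(env)
  p <- fh_profile("ofcom")
  ev <- fh_evaluate_area(fh_merge_synchronous(
    mk_trans(rep(0, 100), rep(1, 100), 1:100), g, 0.02), g, p)
  expect_false(ev$hazardous_area)          # exactly 25%
  ev2 <- fh_evaluate_area(fh_merge_synchronous(
    mk_trans(rep(0, 120), rep(1, 120), 1:120), g, 0.02), g, p)
  expect_true(ev2$hazardous_area)
})

test_that("concentration matters: same area flags inside one window, not dispersed", {
  env <- fh_env(192, 108, px_angular_size = 0.1)
  p <- fh_profile("proposed")
  analyze_disc <- function(spec) {
    gen <- fh_generate(spec, env)
    rep <- fh_analyze(gen$frames, env, profiles = "proposed", extended = FALSE)
    rep$results$proposed
  }
  concentrated <- analyze_disc(fh_pattern("disc", rate = 5, duration = 1,
    fps = 30, base_luminance = 20, magnitude = 40,
    area = list(type = "disc_frac", value = 0.57)))
  expect_false(concentrated$pass)
  # the same total area split into two far-apart discs: no window > 25%
  gen <- fh_generate(fh_pattern("disc", rate = 5, duration = 1, fps = 30,
    base_luminance = 20, magnitude = 40,
    area = list(type = "disc_frac", value = 0.40)), env)
  m <- flashhazard:::.pattern_mask(gen$spec, env)
  # build frames with the disc duplicated at both ends of the frame
  shift <- function(m, dx) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    cols <- which(colSums(m) > 0)
    out[, cols + dx] <- m[, cols]
    out
  }
  m2 <- shift(m, -56) | shift(m, 56)
  lo <- flashhazard:::.gray_code(20, 200); hi <- flashhazard:::.gray_code(60, 200)
  frames <- lapply(0:29, function(k) {
    f <- array(lo, c(108, 192, 3))
    if (floor(10 * k / 30) %% 2 == 1) for (ch in 1:3) f[, , ch][m2] <- hi
    f
  })
  rep <- fh_analyze(fh_frames(frames, fps = 30), env, profiles = "proposed",
                    extended = FALSE)
  ev <- rep$results$proposed$events
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$windowed_fraction <= 0.25))
  expect_true(rep$results$proposed$pass)
})

test_that("halving the window stride never lowers the windowed fraction", {
  env <- fh_env(192, 108, px_angular_size = 0.1)
  gen <- fh_generate(fh_pattern("disc", rate = 5, duration = 0.4, fps = 30,
    base_luminance = 20, magnitude = 40,
    area = list(type = "disc_frac", value = 0.5)), env)
  grid <- fh_build_grid(gen$frames, env)
  p <- fh_profile("proposed")
  tr <- flashhazard:::.grid_transitions(grid, p)
  ev <- fh_merge_synchronous(tr, grid)
  wf_default <- fh_evaluate_area(ev, grid, p)$windowed_fraction[1]
  # a finer stride can only add candidate placements
  W <- fh_window_diameter_px(env, 10)
  centers <- flashhazard:::.window_centers
  c8 <- expand.grid(x = centers(192, W / 2, W / 8), y = centers(108, W / 2, W / 8))
  c16 <- expand.grid(x = centers(192, W / 2, W / 16), y = centers(108, W / 2, W / 16))
  frac_over <- function(cs) {
    blocks <- ev$blocks[[1]]
    bc <- grid$centers[blocks, , drop = FALSE]
    ba <- grid$areas_px2[blocks]
    max(apply(cs, 1, function(cc) {
      inside <- (bc[, 1] - cc[1])^2 + (bc[, 2] - cc[2])^2 <= (W / 2)^2
      sum(ba[inside]) / (pi * (W / 2)^2)
    }))
  }
  f8 <- frac_over(c8); f16 <- frac_over(c16)
  expect_gte(f16, f8)
  expect_lt(abs(f16 - f8) / max(f16, 1e-9), 0.03)
  expect_gte(wf_default + 1e-12, f8)   # centroid placement only helps
})

test_that("NHK classification marks large intermediate changes as scene changes", {
  env <- fh_env(192, 108, px_angular_size = 0.1)
  gen <- fh_generate(fh_pattern("band_flash", rate = 2, duration = 1, fps = 30,
    base_luminance = 20, magnitude = 30, magnitude_units = "ire",
    area = list(type = "fraction", value = 0.85)), env)
  grid <- fh_build_grid(gen$frames, env)
  p <- fh_profile("nhk_jba")
  tr <- flashhazard:::.grid_transitions(grid, p, units = "ire")
  ev <- fh_evaluate_area(fh_merge_synchronous(tr, grid), grid, p, units = "ire")
  expect_true(all(ev$nhk_class == "scene_change"))
  expect_true(all(abs(ev$magnitude - 30) < 1e-6))
})
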