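# Transition detection: qualifying duration, alternation, fast-flash
# merging, and equivalence with the brute-force pairwise oracle.

prof <- fh_profile("proposed")
env200 <- fh_env(16, 9, px_angular_size = 0.1)

test_that("a two-sample 25 cd/m^2 step at 30 fps counts as one transition", {
  L <- c(30, 30, 55, 55, 55)
  tr <- fh_detect_luminance_transitions(L, (0:4) / 30, prof, env200)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$direction, 1)
  expect_equal(tr$time, 2 / 30)
  expect_equal(tr$magnitude, 25)
})

test_that("qualifying duration bounds ramp detection (frame counts 2/4/8)", {
  ramp <- function(n, fps, total = 24, base = 20) {
    lev <- seq(base, base + total, length.out = n)
    list(L = c(base, lev), t = (0:n) / fps)
  }
  # at 30 fps a transition may take 2 samples; at 60 fps, 4; at 120 fps, 8
  for (cfg in list(c(2, 30, 1), c(3, 30, 0),
                   c(4, 60, 1), c(5, 60, 0),
                   c(8, 120, 1), c(9, 120, 0))) {
    r <- ramp(cfg[1], cfg[2], total = if (cfg[1] == 9) 22 else 24)
    tr <- fh_detect_luminance_transitions(r$L, r$t, prof, env200)
    expect_equal(nrow(tr), cfg[3],
                 info = sprintf("%d samples at %d fps", cfg[1], cfg[2]))
  }
})

test_that("non-monotonic excursions count when the net change qualifies", {
  # rises, dips, then exceeds the threshold within the window (4 samples)
  L <- c(20, 32, 28, 42)
  tr <- fh_detect_luminance_transitions(L, (0:3) / 60, prof, env200)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$magnitude, 22)   # net from the anchoring minimum
})

test_that("square-wave counts are frame-rate invariant", {
  counts <- sapply(c(10, 30, 60, 120), function(fps) {
    t <- seq(0, 1 - 1 / fps, by = 1 / fps)
    L <- ifelse(floor(10 * t) %% 2 == 1, 40, 0)   # 5 Hz square wave
    nrow(fh_detect_luminance_transitions(L, t, prof, env200))
  })
  expect_true(all(counts == counts[1]))
  expect_equal(counts[1], 9)   # 10 edges/s; the first edge starts the record
})

test_that("darker-state gating switches to Michelson contrast above 160 cd/m^2", {
  t <- (0:9) / 30
  mk <- function(lo, hi) ifelse(seq_along(t) %% 2 == 0, hi, lo)
  # 21 cd/m^2 on a 165 cd/m^2 darker state: only via the contrast branch
  tr_itu <- fh_detect_luminance_transitions(mk(165, 186), t,
                                            fh_profile("itu_bt1702"), env200)
  tr_iso <- fh_detect_luminance_transitions(mk(165, 186), t,
                                            fh_profile("iso9241_391"), env200)
  expect_gt(nrow(tr_itu), 0)
  expect_equal(nrow(tr_iso), 0)
  # below 1/17 contrast nothing counts anywhere
  tr_lo <- fh_detect_luminance_transitions(mk(165, 180), t,
                                           fh_profile("itu_bt1702"), env200)
  expect_equal(nrow(tr_lo), 0)
})

test_that("scan equals the brute-force all-pairs oracle on random waveforms", {
  p <- fh_profile("wcag2x")
  mismatches <- 0
  for (k in 1:1000) {
    fps <- sample(c(24, 30, 60, 120), 1)
    wf <- random_waveform(n = 40, fps = fps, sd = 18, seed = 31000 + k)
    got <- fh_detect_luminance_transitions(wf$L, wf$times, p, env200)
    want <- oracle_luminance_scan(wf$L, wf$times, Q = 0.066,
                                  diff_cut = 20, dark_cut = 160)
    same <- nrow(got) == nrow(want) &&
      (nrow(got) == 0 || (all(abs(got$time - want$time) < 1e-12) &&
                          all(got$direction == want$direction)))
    if (!same) mismatches <- mismatches + 1
  }
  expect_equal(mismatches, 0)
})

test_that("raising the critical difference never increases the count", {
  set.seed(99)
  for (k in 1:50) {
    wf <- random_waveform(n = 60, fps = 60, sd = 15, seed = 500 + k)
    counts <- sapply(c(10, 20, 35), function(d) {
      p <- fh_profile("itu_bt1702", luminance_diff = d)
      nrow(fh_detect_luminance_transitions(wf$L, wf$times, p, env200))
    })
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("emitted directions strictly alternate", {
  for (k in 1:50) {
    wf <- random_waveform(n = 80, fps = 60, sd = 22, seed = 900 + k)
    tr <- fh_detect_luminance_transitions(wf$L, wf$times, prof, env200)
    if (nrow(tr) > 1) expect_true(all(diff(tr$direction) != 0))
  }
})

test_that("red transitions follow the harmonized and legacy rules", {
  uvof <- function(hex) {
    l <- fh_linearize(fh_hex(hex))
    c(fh_chromaticity(l)$u, fh_chromaticity(l)$v, fh_red_fraction(l),
      fh_wcag20_critical_value(l))
  }
  series <- function(a, b, n = 8) {
    m <- t(sapply(rep(c(a, b), n / 2), uvof))
    list(u = m[, 1], v = m[, 2], rf = m[, 3], cv = m[, 4], t = (0:(n - 1)) / 30)
  }
  # red <-> blue: chromaticity difference 0.457 > 0.2
  s <- series("#FF0000", "#0000FF")
  tr <- fh_detect_red_transitions(s$u, s$v, s$rf, s$cv, s$t, prof)
  expect_equal(nrow(tr), 7)
  expect_true(all(abs(tr$direction) == 1))
  # two saturated reds: no harmonized transition, but a legacy one
  s2 <- series("#FF0000", "#FF3636")
  expect_equal(nrow(fh_detect_red_transitions(s2$u, s2$v, s2$rf, s2$cv, s2$t,
                                              prof)), 0)
  leg <- fh_profile("wcag20_legacy_red")
  expect_gt(nrow(fh_detect_red_transitions(s2$u, s2$v, s2$rf, s2$cv, s2$t,
                                           leg)), 0)
  # identical states never transition
  s3 <- series("#FF0000", "#FF0000")
  expect_equal(nrow(fh_detect_red_transitions(s3$u, s3$v, s3$rf, s3$cv, s3$t,
                                              prof)), 0)
})

test_that("fast flashes merge to two transitions; 50 Hz does not merge", {
  mk <- function(hz, dur = 0.5) {
    times <- seq(0, dur, by = 1 / (2 * hz))
    data.frame(kind = "luminance",
               direction = rep(c(1, -1), length.out = length(times)),
               time = times)
  }
  m100 <- fh_merge_fast_flashes(mk(100), gap = 0.015, placement = "start")
  expect_equal(nrow(m100), 2)
  expect_equal(m100$time, c(0, 0.005))
  m100e <- fh_merge_fast_flashes(mk(100), gap = 0.015, placement = "end")
  expect_equal(nrow(m100e), 2)
  expect_equal(max(m100e$time), 0.5)
  m50 <- fh_merge_fast_flashes(mk(50), gap = 0.015)   # 20 ms spacing
  expect_equal(nrow(m50), nrow(mk(50)))
  single <- mk(100)[1, ]
  expect_equal(nrow(fh_merge_fast_flashes(single, 0.015)), 1)
})

test_that("degenerate series are handled", {
  expect_equal(nrow(fh_detect_luminance_transitions(numeric(0), numeric(0),
                                                    prof, env200)), 0)
  expect_equal(nrow(fh_detect_luminance_transitions(50, 0, prof, env200)), 0)
})
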