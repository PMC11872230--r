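# Window counting, spacing exception, NHK tiers, extended failures, and
# end-to-end determinism.

mk_events <- function(times, dirs = NULL, kind = "luminance",
                      nhk_class = "intermediate") {
  n <- length(times)
  if (is.null(dirs)) dirs <- rep(c(1, -1), length.out = n)
  data.frame(kind = kind, direction = dirs, time = times,
             area_px2 = 100, n_blocks = 100, magnitude = 40, darker = 20,
             michelson = 0.5, screen_fraction = 1, windowed_fraction = 1,
             omega_sr = 0.1, hazardous_area = TRUE, nhk_class = nhk_class)
}

test_that("seven alternating transitions in one second violate; six do not", {
  p <- fh_profile("proposed")
  v7 <- fh_count_violations(mk_events(seq(0, 0.84, by = 0.14)), p)
  expect_equal(nrow(v7), 1)
  expect_equal(v7$count, 7)
  expect_equal(v7$flash_equiv, 3.5)
  v6 <- fh_count_violations(mk_events(seq(0, 1, length.out = 6)), p)
  expect_equal(nrow(v6), 0)
  # 2 Hz flashing never violates regardless of duration
  v2hz <- fh_count_violations(mk_events(seq(0, 5, by = 0.25)), p)
  expect_equal(nrow(v2hz), 0)
})

test_that("only events that pass the area check are counted", {
  p <- fh_profile("proposed")
  ev <- mk_events(seq(0, 0.84, by = 0.14))
  ev$hazardous_area <- FALSE
  expect_equal(nrow(fh_count_violations(ev, p)), 0)
})

test_that("aggregate counting enforces alternation", {
  p <- fh_profile("proposed")
  # ten same-direction events in one second cannot alternate: only the
  # first increments the count
  ev <- mk_events(seq(0, 0.9, by = 0.1), dirs = rep(1, 10))
  expect_equal(nrow(fh_count_violations(ev, p)), 0)
})

test_that("the Ofcom/ITU spacing exception exempts isolated flashes", {
  for (id in c("ofcom", "itu_bt1702")) {
    p <- fh_profile(id)
    # four flashes with 334 ms leading-edge spacing: all isolated
    t8 <- as.vector(rbind(c(0, 0.334, 0.668, 1.002),
                          c(0, 0.334, 0.668, 1.002) + 0.02))
    expect_equal(nrow(fh_count_violations(mk_events(t8), p)), 0)
    # four tightly packed flashes: violation
    t4 <- as.vector(rbind(c(0, 0.1, 0.2, 0.3), c(0, 0.1, 0.2, 0.3) + 0.02))
    expect_gt(nrow(fh_count_violations(mk_events(t4), p)), 0)
  }
  # the same tight flashes also violate without the exception
  expect_gt(nrow(fh_count_violations(
    mk_events(as.vector(rbind(c(0, 0.1, 0.2, 0.3),
                              c(0, 0.1, 0.2, 0.3) + 0.02))),
    fh_profile("proposed"))), 0)
  # a single flash is trivially exempt
  expect_equal(nrow(fh_spacing_exception(mk_events(c(0, 0.02)),
                                         fh_profile("ofcom")$thresholds)), 0)
})

test_that("NHK tiers: moderate rate cap and 2 s persistence, scene changes at 1.5/s", {
  p <- fh_profile("nhk_jba")
  mod <- function(times) mk_events(times, nhk_class = "moderate")
  # 4 flashes/s for 1.5 s: allowed (moderate may reach 5/s for up to 2 s)
  expect_equal(nrow(fh_nhk_verdict(mod(seq(0, 1.4, by = 0.125)), p)), 0)
  # the same rate sustained 3.5 s: violation of the 2 s cap
  expect_gt(nrow(fh_nhk_verdict(mod(seq(0, 3.4, by = 0.125)), p)), 0)
  # 6 flashes/s: above the hard moderate cap
  expect_gt(nrow(fh_nhk_verdict(mod(seq(0, 1, by = 1 / 12)), p)), 0)
  # scene changes: 2 flashes/s violates, 1.5 does not
  sc <- function(times) mk_events(times, nhk_class = "scene_change")
  expect_gt(nrow(fh_nhk_verdict(sc(seq(0, 1, by = 0.25)), p)), 0)
  expect_equal(nrow(fh_nhk_verdict(sc(seq(0, 0.99, by = 1 / 3)), p)), 0)
})

test_that("edge-anchored windows find everything a 1 ms slide finds", {
  set.seed(42)
  for (k in 1:20) {
    times <- sort(runif(sample(5:14, 1), 0, 2))
    ev <- mk_events(times)
    p <- fh_profile("proposed")
    got <- fh_count_violations(ev, p)
    # exhaustive 1 ms slide over alternating events
    alt <- flashhazard:::.alternating(ev)
    slide <- vapply(seq(0, 2, by = 0.001), function(t)
      sum(alt$time >= t & alt$time < t + 1), integer(1))
    expect_equal(nrow(got) > 0, any(slide > 6))
    if (nrow(got) > 0) expect_equal(max(got$count), max(slide))
  }
})

test_that("extended flashing near the limit warns, and violations suppress warnings", {
  env <- fh_env(96, 54, px_angular_size = 0.2)
  # 2.5 Hz full-frame flashing at 0.9x the 20 cd/m^2 threshold for 6 s
  gen <- fh_generate(fh_pattern("uniform_flash", rate = 2.5, duration = 6.5,
                                fps = 30, base_luminance = 20,
                                magnitude = 18), env)
  rep <- fh_analyze(gen$frames, env, profiles = "proposed")
  expect_true(rep$results$proposed$pass)
  expect_gt(nrow(rep$results$proposed$warnings), 0)
  # fully compliant static video: no warnings
  static <- fh_frames(replicate(8, array(0.5, c(54, 96, 3)),
                                simplify = FALSE), fps = 4)
  rep2 <- fh_analyze(static, env, profiles = "proposed")
  expect_true(rep2$results$proposed$pass)
  expect_equal(nrow(rep2$results$proposed$warnings), 0)
  # hard-violating flashing reports the violation, not a warning
  gen3 <- fh_generate(fh_pattern("uniform_flash", rate = 5, duration = 6.5,
                                 fps = 30, base_luminance = 20,
                                 magnitude = 40), env)
  rep3 <- fh_analyze(gen3$frames, env, profiles = "proposed")
  expect_false(rep3$results$proposed$pass)
  expect_equal(nrow(rep3$results$proposed$warnings), 0)
})

test_that("analysis is deterministic and a single transition can count as both kinds", {
  env <- fh_env(96, 54, px_angular_size = 0.2)
  gen <- fh_generate(fh_pattern("red_blue", rate = 12, duration = 1,
                                fps = 60), env)
  r1 <- fh_analyze(gen$frames, env, extended = FALSE)
  r2 <- fh_analyze(gen$frames, env, extended = FALSE)
  j1 <- jsonlite::toJSON(flashhazard:::.report_as_list(r1), auto_unbox = TRUE,
                         digits = NA)
  j2 <- jsonlite::toJSON(flashhazard:::.report_as_list(r2), auto_unbox = TRUE,
                         digits = NA)
  expect_identical(j1, j2)
  # the red-blue alternation (25 cd/m^2 gap) drives both counters
  kinds <- unique(r1$results$proposed$violations$kind)
  expect_setequal(kinds, c("luminance", "red"))
})

test_that("an empty video yields an empty passing report", {
  env <- fh_env(16, 9, px_angular_size = 0.2)
  fs <- fh_frames(replicate(3, array(0.2, c(9, 16, 3)), simplify = FALSE),
                  fps = 30)
  rep <- fh_analyze(fs, env, extended = FALSE)
  expect_true(all(vapply(rep$results, `[[`, logical(1), "pass")))
  expect_true(all(vapply(rep$results, function(r) nrow(r$events) == 0,
                         logical(1))))
})
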