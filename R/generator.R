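# Synthetic test-pattern generator with analytically known ground truth.
#
# Every pattern is constructed in closed form (gray levels chosen to hit
# exact absolute luminances, masks rasterized once), and its expected
# verdict per guideline profile is derived at generation time directly from
# the rule definitions applied to the constructed waveform and mask areas —
# never by running the analyzer. Fixtures are deterministic given the seed.

#' Synthetic pattern specification
#'
#' @param pattern one of `"uniform_flash"`, `"band_flash"` (vertical band
#'   covering a screen fraction), `"disc"`, `"annulus"`, `"target"` (central
#'   disc plus annulus), `"checkerboard_balanced"`,
#'   `"checkerboard_unbalanced"`, `"white_noise"`, `"ramp"`, `"red_blue"`,
#'   `"red_pair"`, `"flash_times"`.
#' @param rate flash rate in Hz (flashes per second; a flash is two
#'   transitions).
#' @param duration seconds.
#' @param fps frames per second.
#' @param base_luminance darker-state luminance, cd/m^2.
#' @param magnitude luminance difference between states (cd/m^2, or IRE
#'   percentage points when `magnitude_units = "ire"`).
#' @param magnitude_units `"cd"` or `"ire"`.
#' @param colors length-2 character of hex colors for `red_*` patterns.
#' @param area list: `list(type = "full")`, `list(type = "fraction", value =
#'   f)` (band), `list(type = "disc_frac", value = f)` (disc diameter as a
#'   fraction of the 10-degree window diameter), `list(type = "disc_px",
#'   value = d)`, or `list(type = "annulus_deg", inner = i, outer = o)`.
#' @param cell_px checkerboard/noise cell size in pixels.
#' @param n_ramp_frames samples in a single luminance ramp (`ramp` pattern).
#' @param monotonic if `FALSE`, the ramp dips in the middle (net change
#'   still `magnitude`).
#' @param flash_times explicit flash leading-edge times (s) for the
#'   `flash_times` pattern; each flash is an up transition at t and a down
#'   transition one frame later.
#' @param jitter_ms amplitude of seeded timestamp jitter (edge-timing
#'   robustness variants).
#' @param seed integer seed for jitter / noise.
#' @return an object of class `fh_pattern`.
#' @export
fh_pattern <- function(pattern, rate = 3, duration = 1, fps = 30,
                       base_luminance = 20, magnitude = 40,
                       magnitude_units = c("cd", "ire"),
                       colors = NULL, area = list(type = "full"),
                       cell_px = 1, n_ramp_frames = 2, monotonic = TRUE,
                       flash_times = NULL, jitter_ms = 0, seed = 1L) {
  pattern <- match.arg(pattern, c("uniform_flash", "band_flash", "disc",
    "annulus", "target", "checkerboard_balanced", "checkerboard_unbalanced",
    "white_noise", "ramp", "red_blue", "red_pair", "flash_times"))
  magnitude_units <- match.arg(magnitude_units)
  stopifnot(duration > 0, fps > 0, rate >= 0)
  structure(as.list(environment()), class = "fh_pattern")
}

# achromatic sRGB code hitting an exact absolute luminance at the reference
.gray_code <- function(L_abs, ref) {
  y <- L_abs / ref
  if (any(y < 0 | y > 1)) stop("luminance outside the displayable range")
  .srgb_compress(y)
}

# rasterized mask (logical H x W) of the flashing region
.pattern_mask <- function(spec, env) {
  w <- env$width_px; h <- env$height_px
  cx <- w / 2; cy <- h / 2
  px <- function(deg) fh_degrees_to_px(deg, env)
  Wd <- fh_window_diameter_px(env, 10)
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 0.5, w), h, w)
  rr <- (xs - cx)^2 + (ys - cy)^2
  a <- spec$area
  switch(spec$pattern,
    band_flash = xs <= round(a$value * w),
    disc = {
      d <- if (identical(a$type, "disc_px")) a$value else a$value * Wd
      rr <= (d / 2)^2
    },
    annulus = rr >= px(a$inner)^2 / 4 & rr <= px(a$outer)^2 / 4,
    target = {
      d5 <- fh_degrees_to_px(fh_solid_angle_to_cone_diameter(0.006), env)
      rr <= (d5 / 2)^2 | (rr >= px(15)^2 / 4 & rr <= px(16.6)^2 / 4)
    },
    matrix(TRUE, h, w))
}

#' Generate a synthetic frame sequence with ground truth
#'
#' @param spec an `fh_pattern`.
#' @param env an `fh_env` (frame dimensions and reference luminance).
#' @return list with `frames` (an `fh_frames`), `truth` (see
#'   [fh_pattern_truth()]) and `spec`.
#' @export
fh_generate <- function(spec, env) {
  stopifnot(inherits(spec, "fh_pattern"), inherits(env, "fh_env"))
  w <- env$width_px; h <- env$height_px
  ref <- env$reference_luminance
  nf <- max(2L, ceiling(spec$duration * spec$fps))
  times <- (seq_len(nf) - 1) / spec$fps
  if (spec$jitter_ms > 0) {
    set.seed(spec$seed)
    j <- runif(nf, -spec$jitter_ms, spec$jitter_ms) / 1000
    j[1] <- 0
    times <- times + j
    times <- cummax(times + seq_len(nf) * 1e-9)   # keep strictly increasing
  }

  gray_frame <- function(code) array(code, dim = c(h, w, 3))
  color_frame <- function(hex) {
    lin <- fh_linearize(fh_hex(hex))$rgb
    enc <- .srgb_compress(lin)
    array(rep(enc, each = h * w), dim = c(h, w, 3))
  }
  mask <- .pattern_mask(spec, env)

  # per-frame binary state of a square wave (leading edges from these)
  sq_state <- function(t) floor(2 * spec$rate * t) %% 2

  frames <- vector("list", nf)
  if (spec$pattern %in% c("uniform_flash", "band_flash", "disc", "annulus",
                          "target")) {
    if (spec$magnitude_units == "ire") {
      c_lo <- spec$base_luminance / 100         # base given as IRE percent
      c_hi <- c_lo + spec$magnitude / 100
      if (c_hi > 1) stop("IRE levels exceed 100%")
    } else {
      c_lo <- .gray_code(spec$base_luminance, ref)
      c_hi <- .gray_code(spec$base_luminance + spec$magnitude, ref)
    }
    st <- sq_state(times)
    for (k in seq_len(nf)) {
      f <- gray_frame(c_lo)
      if (st[k] == 1) for (ch in 1:3) f[, , ch][mask] <- c_hi
      frames[[k]] <- f
    }
  } else if (spec$pattern == "flash_times") {
    if (spec$magnitude_units == "ire") stop("flash_times uses cd magnitudes")
    c_lo <- .gray_code(spec$base_luminance, ref)
    c_hi <- .gray_code(spec$base_luminance + spec$magnitude, ref)
    st <- integer(nf)
    for (ft in spec$flash_times) {
      k <- which(times >= ft - 1e-9)[1]
      if (!is.na(k) && k < nf) st[k] <- 1L     # bright for exactly one frame
    }
    for (k in seq_len(nf)) frames[[k]] <- gray_frame(if (st[k]) c_hi else c_lo)
  } else if (spec$pattern %in% c("checkerboard_balanced",
                                 "checkerboard_unbalanced", "white_noise")) {
    b <- spec$cell_px
    cb <- outer(((seq_len(h) - 1) %/% b), ((seq_len(w) - 1) %/% b), "+") %% 2
    if (spec$pattern == "checkerboard_balanced") {
      c_a <- .gray_code(spec$base_luminance, ref)
      c_b <- .gray_code(spec$base_luminance + spec$magnitude, ref)
      st <- sq_state(times)
      for (k in seq_len(nf)) {
        pat <- ifelse(xor(cb == 1, st[k] == 1), c_a, c_b)
        frames[[k]] <- array(rep(pat, 3), dim = c(h, w, 3))
      }
    } else if (spec$pattern == "checkerboard_unbalanced") {
      # frame A: checkerboard of light and dark gray; frame B: solid light
      c_hi <- .gray_code(spec$base_luminance + spec$magnitude, ref)
      c_lo <- .gray_code(spec$base_luminance, ref)
      st <- sq_state(times)
      for (k in seq_len(nf)) {
        pat <- if (st[k] == 1) matrix(c_hi, h, w) else
          ifelse(cb == 1, c_lo, c_hi)
        frames[[k]] <- array(rep(pat, 3), dim = c(h, w, 3))
      }
    } else {
      # balanced white noise: each analysis block holds a fixed multiset of
      # gray levels, re-permuted every frame, so block means never change
      set.seed(spec$seed)
      bp <- fh_default_block_px(env)
      bi <- .block_index(h, w, bp)
      pix_by_block <- split(seq_len(h * w), bi$idx)
      lv <- seq(0.30, 0.70, length.out = bp * bp)
      for (k in seq_len(nf)) {
        pat <- numeric(h * w)
        for (ii in pix_by_block) pat[ii] <- sample(rep_len(lv, length(ii)))
        frames[[k]] <- array(rep(pat, 3), dim = c(h, w, 3))
      }
    }
  } else if (spec$pattern == "ramp") {
    c_fun <- function(L) .gray_code(L, ref)
    N <- spec$n_ramp_frames
    L0 <- spec$base_luminance; L1 <- L0 + spec$magnitude
    lev <- if (N <= 1) L1 else seq(L0, L1, length.out = N)
    if (!spec$monotonic && N >= 4) {
      mid <- ceiling(N / 2)
      lev[mid] <- lev[mid - 1] - spec$magnitude * 0.1   # mid-ramp dip
    }
    # lead-in hold, ramp, hold at top
    seqL <- c(rep(L0, 2), lev, rep(L1, max(0, nf - N - 2)))[seq_len(nf)]
    for (k in seq_len(nf)) frames[[k]] <- gray_frame(c_fun(seqL[k]))
  } else {                                   # red_blue / red_pair
    cols <- spec$colors
    if (is.null(cols))
      cols <- if (spec$pattern == "red_blue") c("#FF0000", "#2020FF")
              else c("#FF0000", "#FF3636")
    fa <- color_frame(cols[1]); fb <- color_frame(cols[2])
    st <- sq_state(times)
    base <- gray_frame(.gray_code(spec$base_luminance, ref))
    full <- identical(spec$area$type, "full") || is.null(spec$area$type)
    for (k in seq_len(nf)) {
      f <- if (full) {
        if (st[k] == 1) fb else fa
      } else {
        g <- base
        src <- if (st[k] == 1) fb else fa
        for (ch in 1:3) g[, , ch][mask] <- src[, , ch][mask]
        g
      }
      frames[[k]] <- f
    }
  }
  fs <- fh_frames(frames, timestamps = times, space = "sRGB")
  list(frames = fs, truth = fh_pattern_truth(spec, env, mask, times),
       spec = spec)
}

# definitional max count of edges in any 1-s (or len) window anchored at edges
.max_window_count <- function(edges, len = 1) {
  if (!length(edges)) return(0L)
  max(vapply(edges, function(t)
    sum(edges >= t & edges < t + len - 1e-9), integer(1)))
}

#' Ground truth for a synthetic pattern
#'
#' Derives the expected verdict for every guideline profile directly from the
#' rule definitions applied to the constructed stimulus: leading-edge times
#' from the square-wave state sequence, magnitudes from the exact gray
#' levels/colors, areas from the rasterized mask. Independent of the analyzer
#' pipeline.
#'
#' @param spec an `fh_pattern`.
#' @param env the `fh_env` used for generation.
#' @param mask the rasterized flashing-region mask.
#' @param times the frame timestamps actually used.
#' @return list with `expected_violation` (named logical per profile id),
#'   `edges`, `area_px2`, `screen_fraction`, `windowed_fraction`, `cd_mag`,
#'   `ire_mag`, `darker_cd`, `uv_dist`, `legacy_diff`, `red_endpoint`,
#'   `kinds`.
#' @export
fh_pattern_truth <- function(spec, env, mask, times) {
  w <- env$width_px; h <- env$height_px
  ref <- env$reference_luminance
  Wd <- fh_window_diameter_px(env, 10)
  r <- Wd / 2

  # --- edge times from the constructed state sequence -----------------------
  sq_state <- function(t) floor(2 * spec$rate * t) %% 2
  edges <- numeric(0)
  kinds <- "luminance"
  ramp_detected <- FALSE
  if (spec$pattern %in% c("uniform_flash", "band_flash", "disc", "annulus",
                          "target", "checkerboard_balanced",
                          "checkerboard_unbalanced", "red_blue", "red_pair")) {
    st <- sq_state(times)
    edges <- times[which(diff(st) != 0) + 1L]
  } else if (spec$pattern == "flash_times") {
    st <- integer(length(times))
    for (ft in spec$flash_times) {
      k <- which(times >= ft - 1e-9)[1]
      if (!is.na(k) && k < length(times)) st[k] <- 1L
    }
    edges <- times[which(diff(st) != 0) + 1L]
  } else if (spec$pattern == "ramp") {
    # definitional qualifying rule: some sample pair within 66 ms whose net
    # change meets the 20 cd/m^2 critical difference
    N <- spec$n_ramp_frames
    L0 <- spec$base_luminance
    lev <- if (N <= 1) L0 + spec$magnitude else
      seq(L0, L0 + spec$magnitude, length.out = N)
    if (!spec$monotonic && N >= 4) {
      mid <- ceiling(N / 2); lev[mid] <- lev[mid - 1] - spec$magnitude * 0.1
    }
    seqL <- c(rep(L0, 2), lev, rep(L0 + spec$magnitude,
                                   max(0, length(times) - N - 2)))
    seqL <- seqL[seq_along(times)]
    for (j in seq_along(seqL)) {
      ii <- which((times[j] - times <= 0.066 | seq_along(seqL) == j - 1) &
                  seq_along(seqL) < j)
      if (length(ii) && any(seqL[j] - seqL[ii] >= 20)) {
        edges <- times[j]; ramp_detected <- TRUE; break
      }
    }
  }

  # --- magnitudes -----------------------------------------------------------
  is_red <- spec$pattern %in% c("red_blue", "red_pair")
  uv_dist <- legacy_diff <- 0; red_endpoint <- FALSE
  if (is_red) {
    cols <- spec$colors
    if (is.null(cols)) cols <- if (spec$pattern == "red_blue")
      c("#FF0000", "#2020FF") else c("#FF0000", "#FF3636")
    la <- fh_linearize(fh_hex(cols[1])); lb <- fh_linearize(fh_hex(cols[2]))
    uv_dist <- fh_uv_distance(fh_chromaticity(la), fh_chromaticity(lb))
    legacy_diff <- abs(fh_wcag20_critical_value(la) - fh_wcag20_critical_value(lb))
    red_endpoint <- max(fh_red_fraction(la), fh_red_fraction(lb)) >= 0.8 - 1e-9
    L <- ref * c(fh_relative_luminance(la), fh_relative_luminance(lb))
    cd_mag <- abs(diff(L)); darker <- min(L)
    enc <- rbind(.srgb_compress(la$rgb), .srgb_compress(lb$rgb))
    ire_mag <- 100 * abs(diff(enc %*% .space_luma_weights("sRGB")))[1]
    kinds <- c("luminance", "red")
  } else if (spec$magnitude_units == "ire") {
    c_lo <- spec$base_luminance / 100; c_hi <- c_lo + spec$magnitude / 100
    L <- ref * .srgb_expand(c(c_lo, c_hi))
    cd_mag <- diff(L); darker <- L[1]; ire_mag <- spec$magnitude
  } else {
    darker <- spec$base_luminance
    cd_mag <- spec$magnitude
    ire_mag <- 100 * abs(.gray_code(darker + cd_mag, ref) - .gray_code(darker, ref))
    if (spec$pattern == "checkerboard_unbalanced") {
      # block means swing by half the cell swing, in linear and encoded terms
      ire_mag <- 100 * (.gray_code(darker + cd_mag, ref) -
                        .gray_code(darker, ref)) / 2
      cd_mag <- spec$magnitude / 2
      darker <- spec$base_luminance + spec$magnitude / 2
    }
  }
  if (spec$pattern %in% c("checkerboard_balanced", "white_noise")) {
    edges <- numeric(0)                     # balanced at analysis-block scale
    cd_mag <- 0; ire_mag <- 0
  }

  # --- areas ----------------------------------------------------------------
  full_at_block_scale <- spec$pattern %in%
    c("uniform_flash", "flash_times", "ramp", "checkerboard_unbalanced") ||
    (is_red && (is.null(spec$area$type) || identical(spec$area$type, "full")))
  area_px2 <- if (full_at_block_scale) w * h else sum(mask)
  sf <- area_px2 / (w * h)
  window_area <- pi * r^2
  wf <- if (full_at_block_scale) 1 else switch(spec$area$type,
    fraction = {
      wb <- round(spec$area$value * w)
      cx <- max(r, min(w - r, wb / 2))      # best on-screen placement
      a2 <- wb - cx                         # band edge relative to center
      a2 <- max(-r, min(r, a2))
      (r^2 * (asin(a2 / r) + pi / 2) + a2 * sqrt(r^2 - a2^2)) / window_area
    },
    disc_frac = , disc_px = min(1, area_px2 / window_area),
    NA_real_)

  # --- per-profile rule evaluation -----------------------------------------
  Q_ok <- if (spec$pattern == "ramp") ramp_detected else TRUE
  lum_counts <- function(id) {
    if (!Q_ok || cd_mag <= 0) return(FALSE)
    if (id == "nhk_jba") return(ire_mag >= 10)
    if (darker < 160) return(cd_mag >= 20)
    if (id %in% c("proposed", "itu_bt1702"))
      return(cd_mag / (2 * darker + cd_mag) >= 1 / 17)
    FALSE
  }
  red_counts <- function(id) {
    if (!is_red || !Q_ok || !red_endpoint) return(FALSE)
    if (id == "wcag20_legacy_red") legacy_diff > 20 else uv_dist > 0.2
  }
  area_ok <- function(id) {
    if (id %in% c("proposed", "wcag2x", "wcag20_legacy_red")) {
      if (is.na(wf)) NA else wf > 0.25
    } else sf > 0.25
  }
  rate_violation <- function(id) {
    e <- edges
    if (length(e) < 7) {
      if (id != "nhk_jba") return(FALSE)
    }
    if (id == "proposed" && length(e) >= 4) {
      gaps <- diff(e[seq(1, length(e), by = 2)])
      if (length(gaps) && all(gaps <= 0.015)) e <- e[c(1, 2)]  # fast-flash merge
    }
    if (id %in% c("ofcom", "itu_bt1702") && length(e) >= 2) {
      fl <- e[seq(1, length(e), by = 2)]
      gp <- c(Inf, diff(fl)); gn <- c(diff(fl), Inf)
      keep <- !(gp >= 0.334 & gn >= 0.334)
      e <- sort(unlist(lapply(which(keep), function(k) {
        i <- 2 * k - 1; c(e[i], if (i + 1 <= length(e)) e[i + 1])
      })))
    }
    if (id == "nhk_jba") {
      tier <- if (ire_mag >= 20) "intermediate" else if (ire_mag >= 10)
        "moderate" else "none"
      if (tier == "intermediate" && sf >= 0.8) tier <- "scene"
      return(switch(tier,
        none = FALSE,
        scene = .max_window_count(e) > 3,
        intermediate = .max_window_count(e) > 6,
        moderate = {
          ep <- cumsum(c(TRUE, diff(e) >= 1 / 6))
          long_ep <- any(vapply(split(e, ep), function(g)
            length(g) > 1 && diff(range(g)) > 2, logical(1)))
          .max_window_count(e) > 10 || long_ep
        }))
    }
    .max_window_count(e) > 6
  }

  ids <- c("proposed", "wcag2x", "wcag20_legacy_red", "iso9241_391",
           "itu_bt1702", "ofcom", "nhk_jba")
  viol <- vapply(ids, function(id) {
    lum0 <- lum_counts(id); red0 <- red_counts(id)
    if (!lum0 && !red0) return(FALSE)
    a <- area_ok(id)
    if (is.na(a)) return(NA)
    lum <- lum0 && a && rate_violation(id)
    red <- red0 && a &&
      (if (id == "nhk_jba") .max_window_count(edges) > 6 else rate_violation(id))
    lum || red
  }, logical(1))

  list(expected_violation = viol, edges = edges,
       expected_transitions = length(edges),
       area_px2 = area_px2, screen_fraction = sf, windowed_fraction = wf,
       cd_mag = cd_mag, ire_mag = ire_mag, darker_cd = darker,
       uv_dist = uv_dist, legacy_diff = legacy_diff,
       red_endpoint = red_endpoint, kinds = kinds)
}

#' Generate the fixture catalog
#'
#' A fixed catalog of ~40 synthetic fixtures gridding flash rate, magnitude,
#' darker-state level, area and color across the threshold boundaries (one
#' step below / at / one step above), each with analytically derived
#' per-profile expected verdicts. Deterministic given the seed.
#'
#' @param env base `fh_env` for the catalog (default: a 192x108 frame at
#'   0.1 degrees/px, i.e. a 19x11 degree field). Fine-pattern fixtures use a
#'   finer 0.025 degrees/px variant of the same frame so that analysis
#'   blocks (0.1 degrees) span multiple pattern cells.
#' @param seed integer seed (jitter variants).
#' @param patterns optional subset of entry names.
#' @return list of entries, each `list(name, spec, env)`; pass entries to
#'   [fh_generate()].
#' @export
fh_generate_catalog <- function(env = NULL, seed = 1L, patterns = NULL) {
  if (is.null(env)) env <- fh_env(192, 108, px_angular_size = 0.1)
  fine <- fh_env(env$width_px, env$height_px,
                 px_angular_size = env$px_angular_size / 4)
  e <- list(); add <- function(name, spec, en = env)
    e[[length(e) + 1L]] <<- list(name = name, spec = spec, env = en)

  # rate axis (full-field 40 cd/m^2 swings)
  for (rt in c(1.25, 3, 3.5, 5, 8))
    add(paste0("rate_", rt), fh_pattern("uniform_flash", rate = rt,
        duration = 2, fps = 60, base_luminance = 20, magnitude = 40,
        seed = seed))
  # magnitude axis at 5 Hz
  for (m in c(10, 19, 20, 21, 60))
    add(paste0("mag_", m), fh_pattern("uniform_flash", rate = 5,
        duration = 2, fps = 60, base_luminance = 20, magnitude = m,
        seed = seed))
  # darker-state gate and the Michelson bright branch
  add("dark_150_171", fh_pattern("uniform_flash", rate = 5, duration = 2,
      fps = 60, base_luminance = 150, magnitude = 21, seed = seed))
  add("bright_165_186", fh_pattern("uniform_flash", rate = 5, duration = 2,
      fps = 60, base_luminance = 165, magnitude = 21, seed = seed))
  add("bright_165_180", fh_pattern("uniform_flash", rate = 5, duration = 2,
      fps = 60, base_luminance = 165, magnitude = 15, seed = seed))
  # screen-fraction axis (vertical bands; boundary at exactly 25%)
  for (f in c(0.20, 0.25, 0.30, 0.50))
    add(paste0("band_", f), fh_pattern("band_flash", rate = 5, duration = 2,
        fps = 60, base_luminance = 20, magnitude = 40,
        area = list(type = "fraction", value = f), seed = seed))
  # windowed-area axis (centered discs, diameter as fraction of 10-deg window)
  for (f in c(0.30, 0.48, 0.52, 0.80))
    add(paste0("disc_", f), fh_pattern("disc", rate = 5, duration = 2,
        fps = 60, base_luminance = 20, magnitude = 40,
        area = list(type = "disc_frac", value = f), seed = seed))
  # red axis
  add("red_blue_12hz", fh_pattern("red_blue", rate = 12, duration = 2,
      fps = 60, seed = seed))
  add("red_blue_1.25hz", fh_pattern("red_blue", rate = 1.25, duration = 2,
      fps = 60, seed = seed))
  add("legacy_red_5hz", fh_pattern("red_pair", rate = 5, duration = 2,
      fps = 60, colors = c("#FF0000", "#FF3636"), seed = seed))
  add("red_uv_below", fh_pattern("red_pair", rate = 5, duration = 2,
      fps = 60, colors = c("#FF0000", .red_mix_at_uv_distance(0.19)),
      seed = seed))
  add("red_uv_above", fh_pattern("red_pair", rate = 5, duration = 2,
      fps = 60, colors = c("#FF0000", .red_mix_at_uv_distance(0.21)),
      seed = seed))
  # temporal axis
  add("ramp_4_at_60", fh_pattern("ramp", fps = 60, duration = 0.5,
      base_luminance = 20, magnitude = 24, n_ramp_frames = 4, seed = seed))
  add("ramp_5_at_60", fh_pattern("ramp", fps = 60, duration = 0.5,
      base_luminance = 20, magnitude = 24, n_ramp_frames = 5, seed = seed))
  add("ramp_8_at_120", fh_pattern("ramp", fps = 120, duration = 0.5,
      base_luminance = 20, magnitude = 24, n_ramp_frames = 8, seed = seed))
  add("ramp_9_at_120", fh_pattern("ramp", fps = 120, duration = 0.5,
      base_luminance = 20, magnitude = 22, n_ramp_frames = 9, seed = seed))
  add("fast_100hz", fh_pattern("uniform_flash", rate = 100, duration = 0.5,
      fps = 240, base_luminance = 20, magnitude = 40, seed = seed))
  add("fast_50hz", fh_pattern("uniform_flash", rate = 50, duration = 0.5,
      fps = 240, base_luminance = 20, magnitude = 40, seed = seed))
  add("paced_334ms", fh_pattern("flash_times", fps = 60, duration = 1.6,
      base_luminance = 20, magnitude = 40,
      flash_times = c(0.1, 0.45, 0.8, 1.15, 1.5), seed = seed))
  add("bursts_100ms", fh_pattern("flash_times", fps = 60, duration = 1.2,
      base_luminance = 20, magnitude = 40,
      flash_times = c(0.1, 0.2, 0.3, 0.4), seed = seed))
  add("jitter_3.5hz", fh_pattern("uniform_flash", rate = 3.5, duration = 2,
      fps = 60, base_luminance = 20, magnitude = 40, jitter_ms = 2,
      seed = seed))
  # fine patterns (analysis blocks span multiple cells)
  add("checker_balanced", fh_pattern("checkerboard_balanced", rate = 10,
      duration = 1, fps = 30, base_luminance = 20, magnitude = 44,
      cell_px = 2, seed = seed), fine)
  add("checker_unbalanced", fh_pattern("checkerboard_unbalanced", rate = 5,
      duration = 2, fps = 30, base_luminance = 20, magnitude = 44,
      cell_px = 2, seed = seed), fine)
  add("white_noise", fh_pattern("white_noise", rate = 10, duration = 1,
      fps = 30, cell_px = 1, seed = seed), fine)
  # NHK tiers (IRE units)
  add("nhk_moderate_ok", fh_pattern("uniform_flash", rate = 4,
      duration = 1.5, fps = 60, base_luminance = 35, magnitude = 15,
      magnitude_units = "ire", seed = seed))
  add("nhk_moderate_long", fh_pattern("uniform_flash", rate = 4,
      duration = 3.5, fps = 60, base_luminance = 35, magnitude = 15,
      magnitude_units = "ire", seed = seed))
  add("nhk_moderate_fast", fh_pattern("uniform_flash", rate = 6,
      duration = 1.5, fps = 60, base_luminance = 35, magnitude = 15,
      magnitude_units = "ire", seed = seed))
  add("nhk_scene_2hz", fh_pattern("band_flash", rate = 2, duration = 2,
      fps = 60, base_luminance = 20, magnitude = 30, magnitude_units = "ire",
      area = list(type = "fraction", value = 0.85), seed = seed))
  add("nhk_scene_1.25hz", fh_pattern("band_flash", rate = 1.25, duration = 2,
      fps = 60, base_luminance = 20, magnitude = 30, magnitude_units = "ire",
      area = list(type = "fraction", value = 0.85), seed = seed))

  names(e) <- vapply(e, `[[`, "", "name")
  if (!is.null(patterns)) e <- e[patterns]
  e
}

# mix of pure red toward blue whose u'v' distance from #FF0000 equals d
# (solved deterministically; the mixed state stays saturated red)
.red_mix_at_uv_distance <- function(d) {
  red <- fh_chromaticity(fh_linearize(fh_hex("#FF0000")))
  f <- function(b) {
    ch <- fh_chromaticity(structure(list(rgb = c(1, 0, b), space = "sRGB"),
                                    class = "fh_linear"))
    fh_uv_distance(red, ch) - d
  }
  b <- uniroot(f, c(1e-6, 1), tol = 1e-10)$root
  code <- round(.srgb_compress(b) * 255)
  sprintf("#FF00%02X", code)
}
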