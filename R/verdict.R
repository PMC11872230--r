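# Sliding-window counting and per-profile verdicts.
#
# A flash is a pair of opposite transitions; the shared limit is "no more
# than 3 flashes in any 1 s span", i.e. a violation when more than 6
# alternating transition counts fall inside a 1 s window. Counts are
# piecewise constant between event edges, so anchoring candidate windows at
# the edges finds every window a continuous slide would find.

# events with time in [t, t + len); the upper bound is shaved by 1 ns so a
# frame landing exactly on the open boundary is never pulled in by rounding
.window_count <- function(times, t, len = 1)
  sum(times >= t & times < t + len - 1e-9)

# greedy maximal alternating-direction subsequence (aggregate alternation)
.alternating <- function(ev) {
  if (!nrow(ev)) return(ev)
  keep <- logical(nrow(ev))
  last <- 0
  for (i in seq_len(nrow(ev))) {
    if (ev$direction[i] != last) { keep[i] <- TRUE; last <- ev$direction[i] }
  }
  ev[keep, , drop = FALSE]
}

#' Count rate violations over 1-second windows
#'
#' Considers only events that passed the area check, enforces alternation on
#' the aggregate event sequence per kind, optionally merges fast flashes
#' (both placements analyzed, the worse one reported), applies the
#' Ofcom/ITU-R leading-edge spacing exception where the profile carries it,
#' and then flags every 1 s window holding more than `2 * flashes_per_s`
#' transitions.
#'
#' @param events evaluated events from [fh_evaluate_area()].
#' @param profile an `fh_profile`.
#' @return data.frame of violations: `profile`, `kind`, `t_start`, `t_end`,
#'   `count`, `flash_equiv`.
#' @export
fh_count_violations <- function(events, profile) {
  th <- profile$thresholds
  out <- .empty_violations()
  ev0 <- events[events$hazardous_area, , drop = FALSE]
  for (kind in unique(ev0$kind)) {
    ev <- .alternating(ev0[ev0$kind == kind, , drop = FALSE])
    seqs <- if (isTRUE(th$fast_merge) && nrow(ev) >= 3) {
      list(fh_merge_fast_flashes(ev, th$fast_flash_gap, "start"),
           fh_merge_fast_flashes(ev, th$fast_flash_gap, "end"))
    } else list(ev)
    best <- NULL
    for (s in seqs) {
      if (isTRUE(th$spacing_exception)) s <- fh_spacing_exception(s, th)
      v <- .rate_violations(s$time, 2 * th$flashes_per_s, profile$id, kind)
      if (is.null(best) || nrow(v) > nrow(best) ||
          (nrow(v) && nrow(best) && max(v$count) > max(best$count))) best <- v
    }
    out <- rbind(out, best)
  }
  out
}

.empty_violations <- function() {
  data.frame(profile = character(), kind = character(), t_start = numeric(),
             t_end = numeric(), count = integer(), flash_equiv = numeric())
}

.rate_violations <- function(times, limit, profile_id, kind, len = 1) {
  out <- .empty_violations()
  for (t in unique(times)) {
    cnt <- .window_count(times, t, len)
    if (cnt > limit)
      out <- rbind(out, data.frame(profile = profile_id, kind = kind,
                                   t_start = t, t_end = t + len,
                                   count = cnt, flash_equiv = cnt / 2))
  }
  out
}

#' Apply the Ofcom/ITU-R flash-spacing exception
#'
#' Flashes whose leading edges are separated from both neighbouring flashes
#' by at least the environment's bound (334 ms in a 60 Hz environment,
#' 360 ms at 50 Hz) are acceptable and removed from counting.
#'
#' @param events alternating event data.frame for one kind.
#' @param th threshold list of the profile.
#' @return events with exempt flashes' transitions removed.
#' @export
fh_spacing_exception <- function(events, th) {
  n <- nrow(events)
  if (n < 2) return(events[0, , drop = FALSE])
  # pair transitions into flashes: (1,2), (3,4), ...
  starts <- seq(1L, n, by = 2L)
  ft <- events$time[starts]
  m <- length(ft)
  gap_prev <- c(Inf, diff(ft))
  gap_next <- c(diff(ft), Inf)
  exempt <- gap_prev >= th$spacing_bound & gap_next >= th$spacing_bound
  keep_rows <- unlist(lapply(which(!exempt), function(k) {
    i <- starts[k]; c(i, if (i + 1L <= n) i + 1L)
  }))
  events[sort(keep_rows), , drop = FALSE]
}

#' NHK/JBA rate verdict
#'
#' Tiered rates: scene changes (intermediate-or-greater magnitude on at
#' least 80% of the screen) are limited to 1.5 flashes/s; intermediate
#' flashing to 3 flashes/s; moderate flashing may reach 5 flashes/s but only
#' for spans of up to 2 s (and 3 flashes/s thereafter). The 2 s cap is
#' evaluated as a rolling episode rule: transitions closer together than the
#' 3 flashes/s spacing (1/6 s) form an episode, and an episode longer than
#' 2 s is a violation. Red transitions keep the common 3 flashes/s limit.
#'
#' @param events evaluated events (with `nhk_class`) from
#'   [fh_evaluate_area()].
#' @param profile the `nhk_jba` profile.
#' @return violations data.frame.
#' @export
fh_nhk_verdict <- function(events, profile) {
  th <- profile$thresholds
  out <- .empty_violations()
  ev0 <- events[events$hazardous_area, , drop = FALSE]

  red <- .alternating(ev0[ev0$kind == "red", , drop = FALSE])
  out <- rbind(out, .rate_violations(red$time, 2 * th$flashes_per_s,
                                     profile$id, "red"))

  lum <- .alternating(ev0[ev0$kind == "luminance", , drop = FALSE])
  scene <- lum[lum$nhk_class == "scene_change", , drop = FALSE]
  inter <- lum[lum$nhk_class == "intermediate", , drop = FALSE]
  moder <- lum[lum$nhk_class == "moderate", , drop = FALSE]

  sv <- .rate_violations(scene$time, 2 * th$nhk_scene_rate, profile$id,
                         "scene_change")
  out <- rbind(out, sv)
  out <- rbind(out, .rate_violations(inter$time, 2 * th$flashes_per_s,
                                     profile$id, "luminance"))
  # moderate: hard cap 5 flashes/s …
  out <- rbind(out, .rate_violations(moder$time, 2 * th$nhk_moderate_rate,
                                     profile$id, "luminance"))
  # … and the 2 s cap: an episode of moderate flashing faster than the
  # 3 flashes/s base rate (successive transitions closer than 1/6 s) may
  # last at most 2 s
  if (nrow(moder) > 1) {
    gap_cut <- 1 / (2 * th$flashes_per_s)
    ep <- cumsum(c(TRUE, diff(moder$time) >= gap_cut))
    for (g in split(moder$time, ep)) {
      if (length(g) > 1 && diff(range(g)) > th$nhk_moderate_cap_s)
        out <- rbind(out, data.frame(profile = profile$id, kind = "luminance",
                                     t_start = min(g), t_end = max(g),
                                     count = length(g),
                                     flash_equiv = length(g) / 2))
    }
  }
  out
}

#' Extended-failure scan
#'
#' A non-normative heuristic for cumulative, just-below-threshold flashing:
#' a warning (never a hard violation) when, over any 5 s window, at least
#' 80% of frames participate in flashing at 0.8x of the magnitude and area
#' thresholds with at least 2 flashes/s. Warnings overlapping a hard
#' violation are suppressed.
#'
#' @param near_events events detected with the scaled-down thresholds.
#' @param frame_times frame timestamps (s).
#' @param violations hard violations already found.
#' @param profile an `fh_profile`.
#' @return data.frame of warnings: `t_start`, `t_end`, `frame_fraction`,
#'   `rate`.
#' @export
fh_extended_failure_scan <- function(near_events, frame_times, violations,
                                     profile) {
  th <- profile$thresholds
  out <- data.frame(t_start = numeric(), t_end = numeric(),
                    frame_fraction = numeric(), rate = numeric())
  ne <- near_events[near_events$hazardous_area, , drop = FALSE]
  if (nrow(ne) < 2) return(out)
  W <- th$extended_window_s
  half_gap <- 1 / (2 * th$extended_min_rate)
  for (t in unique(c(ne$time, frame_times[1]))) {
    if (t + W > max(frame_times) + 1e-9) next
    fr <- frame_times[frame_times >= t & frame_times < t + W]
    if (!length(fr)) next
    edges <- ne$time[ne$time >= t & ne$time < t + W]
    part <- vapply(fr, function(f) any(abs(edges - f) <= half_gap), logical(1))
    frac <- mean(part)
    rate <- length(edges) / 2 / W
    if (frac >= th$extended_frame_frac && rate >= th$extended_min_rate) {
      overlap <- nrow(violations) &&
        any(violations$t_start < t + W & violations$t_end > t)
      if (!overlap)
        out <- rbind(out, data.frame(t_start = t, t_end = t + W,
                                     frame_fraction = frac, rate = rate))
    }
  }
  out[!duplicated(round(out$t_start, 6)), , drop = FALSE]
}

#' Analyze a frame sequence against guideline profiles
#'
#' End-to-end pipeline: build the analysis grid, detect per-block luminance
#' and red transitions, merge synchronous areas into events, evaluate area
#' thresholds, and count rate violations per profile. Deterministic: the same
#' input and configuration produce an identical report.
#'
#' @param fs an `fh_frames` (or a list of frames plus `fps` via `...`).
#' @param env an `fh_env`; default CSS reference preset.
#' @param profiles character vector of profile ids or list of `fh_profile`s;
#'   default all seven.
#' @param block_px analysis block size override.
#' @param extended run the extended-failure heuristic (default TRUE for
#'   profiles of guidelines that mention extended flashing).
#' @param ... passed to [fh_frames()] when `fs` is a raw frame list.
#' @return an object of class `fh_report`.
#' @export
fh_analyze <- function(fs, env = fh_env_preset("css-reference"),
                       profiles = NULL, block_px = NULL, extended = TRUE, ...) {
  if (!inherits(fs, "fh_frames")) fs <- fh_frames(fs, ...)
  if (is.null(profiles)) profiles <- fh_all_profiles()
  if (is.character(profiles)) profiles <- setNames(lapply(profiles, fh_profile),
                                                  profiles)
  if (inherits(profiles, "fh_profile")) profiles <- setNames(
    list(profiles), profiles$id)
  grid <- fh_build_grid(fs, env, block_px = block_px)
  sdr <- fs$space %in% c("sRGB", "BT.1886", "BT.2020-SDR")
  res <- list()
  for (nm in names(profiles)) {
    p <- profiles[[nm]]
    units <- if (isTRUE(p$thresholds$nhk) && sdr) "ire" else "cd"
    trans <- .grid_transitions(grid, p, units = units)
    ev <- fh_merge_synchronous(trans, grid, p$thresholds$sync_window)
    ev <- fh_evaluate_area(ev, grid, p, units = units)
    viol <- if (isTRUE(p$thresholds$nhk)) fh_nhk_verdict(ev, p)
            else fh_count_violations(ev, p)
    warns <- NULL
    if (extended && p$id %in% c("proposed", "iso9241_391", "itu_bt1702",
                                "ofcom")) {
      f <- p$thresholds$extended_factor
      near <- fh_profile(p$id,
        luminance_diff = p$thresholds$luminance_diff * f,
        wcag_rel_diff = p$thresholds$wcag_rel_diff * f,
        red_uv_diff = p$thresholds$red_uv_diff * f,
        area_fraction = p$thresholds$area_fraction * f)
      ntr <- .grid_transitions(grid, near, units = units)
      nev <- fh_merge_synchronous(ntr, grid, near$thresholds$sync_window)
      nev <- fh_evaluate_area(nev, grid, near, units = units)
      warns <- fh_extended_failure_scan(nev, grid$times, viol, p)
    }
    res[[nm]] <- list(profile = p, events = ev, violations = viol,
                      warnings = warns,
                      pass = nrow(viol) == 0)
  }
  structure(list(
    input = list(n_frames = length(fs$frames), width = fs$width,
                 height = fs$height, space = fs$space,
                 duration_s = diff(range(fs$timestamps))),
    env = env, block_px = grid$block_px,
    results = res), class = "fh_report")
}

#' @export
print.fh_report <- function(x, ...) {
  cat(sprintf("<fh_report> %d frames %dx%d [%s], %.2f s, block %d px\n",
              x$input$n_frames, x$input$width, x$input$height, x$input$space,
              x$input$duration_s, x$block_px))
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    nw <- if (is.null(r$warnings)) 0L else nrow(r$warnings)
    cat(sprintf("  %-18s %s  (%d violation%s, %d warning%s)\n", nm,
                if (r$pass) "PASS" else "FAIL",
                nrow(r$violations), if (nrow(r$violations) == 1) "" else "s",
                nw, if (nw == 1) "" else "s"))
  }
  invisible(x)
}

#' @export
summary.fh_report <- function(object, ...) {
  v <- do.call(rbind, lapply(object$results, `[[`, "violations"))
  cat("Violations:\n")
  if (is.null(v) || !nrow(v)) cat("  none\n") else print(v, row.names = FALSE)
  invisible(v)
}
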