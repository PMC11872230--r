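# Per-block transition detection.
#
# A countable transition is a change that (a) equals or exceeds the critical
# transition difference, (b) evolves over no more than the qualifying
# duration (66 ms working value; an N-sample ramp spans N-1 frame intervals,
# and a change between adjacent samples is an instantaneous cut that always
# qualifies),
# and (c) alternates in direction with the previous transition of the same
# kind. The scan tracks the running extremum since the last counted
# transition, so non-monotonic excursions count when the *net* change meets
# the threshold inside the window. The leading edge is the time of the sample
# at which the cumulative change first meets the threshold.

# Gating closure for luminance transitions. darker/brighter in the units of
# the series (cd/m^2, relative luminance, or IRE percent).
.lum_gate <- function(th, hdr_contrast, dark_cut, diff_cut) {
  force(th); force(hdr_contrast); force(dark_cut); force(diff_cut)
  function(darker, brighter) {
    if (darker < dark_cut) return((brighter - darker) >= diff_cut)
    if (!hdr_contrast) return(FALSE)
    fh_michelson(brighter, darker) >= th$bright_state_contrast
  }
}

#' Detect luminance transitions in one series
#'
#' Extremum-tracking scan over a single block's luminance time series.
#'
#' @param L numeric luminance series (absolute cd/m^2 unless `units` says
#'   otherwise).
#' @param times sample times in seconds, strictly increasing.
#' @param profile an `fh_profile`.
#' @param env an `fh_env` (supplies the reference luminance for the
#'   proposed/WCAG relative gating).
#' @param units `"cd"` (default), `"relative"`, or `"ire"`; selects the
#'   gating scale.
#' @return data.frame with columns `kind`, `direction` (+1 up / -1 down),
#'   `time` (leading edge), `anchor_time`, `span`, `magnitude`, `pre`, `post`.
#' @export
fh_detect_luminance_transitions <- function(L, times, profile, env = NULL,
                                            units = c("cd", "relative", "ire")) {
  units <- match.arg(units)
  th <- profile$thresholds
  ref <- if (!is.null(env)) env$reference_luminance else 200
  gate <- switch(units,
    cd = if (profile$id %in% c("proposed", "wcag2x", "wcag20_legacy_red"))
      # thresholds defined as fractions of the reference luminance
      .lum_gate(th, profile$hdr_contrast,
                th$wcag_dark_cut * ref, th$wcag_rel_diff * ref)
    else
      .lum_gate(th, profile$hdr_contrast, th$dark_state_cut, th$luminance_diff),
    relative = .lum_gate(th, profile$hdr_contrast, th$wcag_dark_cut, th$wcag_rel_diff),
    ire = .lum_gate(th, FALSE, Inf, th$nhk_moderate_ire[1]))
  .scan_extremum(L, times, th$qualifying_duration, gate)
}

# The scan itself, shared by units. gate(darker, brighter) -> logical.
.scan_extremum <- function(L, times, Q, gate) {
  n <- length(L)
  empty <- data.frame(kind = character(), direction = numeric(),
                      time = numeric(), anchor_time = numeric(),
                      span = numeric(), magnitude = numeric(),
                      pre = numeric(), post = numeric())
  if (n < 2) return(empty)
  out <- vector("list", 0L)
  anchor <- 1L      # first index eligible as a pre-state
  last_dir <- 0
  j <- 2L
  while (j <= n) {
    lo <- anchor
    while (times[j] - times[lo] > Q) lo <- lo + 1L
    # a change between adjacent samples is an instantaneous cut and always
    # qualifies; the 66 ms window bounds multi-sample evolution
    if (lo > j - 1L) lo <- j - 1L
    rec <- NULL
    if (lo <= j - 1L) {
      win <- lo:(j - 1L)
      up <- dn <- NULL
      if (last_dir <= 0) {                       # candidate up transition
        i <- win[which.min(L[win])]
        if (L[j] > L[i] && gate(L[i], L[j]))
          up <- list(dir = 1, i = i, mag = L[j] - L[i])
      }
      if (last_dir >= 0) {                       # candidate down transition
        i <- win[which.max(L[win])]
        if (L[j] < L[i] && gate(L[j], L[i]))
          dn <- list(dir = -1, i = i, mag = L[i] - L[j])
      }
      rec <- if (is.null(up)) dn else if (is.null(dn)) up
             else if (up$mag >= dn$mag) up else dn
    }
    if (!is.null(rec)) {
      out[[length(out) + 1L]] <- data.frame(
        kind = "luminance", direction = rec$dir,
        time = times[j], anchor_time = times[rec$i],
        span = times[j] - times[rec$i], magnitude = rec$mag,
        pre = L[rec$i], post = L[j])
      anchor <- j
      last_dir <- rec$dir
    }
    j <- j + 1L
  }
  if (!length(out)) empty else do.call(rbind, out)
}

#' Detect red transitions in one series
#'
#' Harmonized mode: a transition needs one saturated-red endpoint
#' (linear R/(R+G+B) >= 0.8) and a u'v' chromaticity difference strictly
#' greater than 0.2, within the qualifying duration. Legacy WCAG 2.0/2.1 mode
#' instead requires the legacy critical values to differ by more than 20
#' (black endpoints allowed, since the legacy value is defined at black).
#' Direction is to-red (+1) / away-from-red (-1); directions alternate.
#'
#' @param u,v chromaticity series (NA where undefined).
#' @param redfrac saturated-red fraction series (NA at black).
#' @param legacy_cv legacy critical-value series.
#' @param times sample times (s), strictly increasing.
#' @param profile an `fh_profile`; `thresholds$legacy_red` selects the mode.
#' @return data.frame as in [fh_detect_luminance_transitions()] with
#'   `kind = "red"`; `magnitude` is the u'v' distance (or legacy value
#'   difference in legacy mode).
#' @export
fh_detect_red_transitions <- function(u, v, redfrac, legacy_cv, times, profile) {
  th <- profile$thresholds
  legacy <- isTRUE(th$legacy_red)
  Q <- th$qualifying_duration
  n <- length(times)
  empty <- data.frame(kind = character(), direction = numeric(),
                      time = numeric(), anchor_time = numeric(),
                      span = numeric(), magnitude = numeric(),
                      pre = numeric(), post = numeric())
  if (n < 2) return(empty)
  # the 0.8 cut is compared with a 1e-9 guard: colors whose fraction is
  # exactly 0.8 in exact arithmetic (e.g. very dark reds hitting the linear
  # segment) can land one ulp below it in doubles
  isred <- !is.na(redfrac) & redfrac >= th$red_sat_cut - 1e-9
  out <- vector("list", 0L)
  anchor <- 1L; last_dir <- 0
  j <- 2L
  while (j <= n) {
    lo <- anchor
    while (times[j] - times[lo] > Q) lo <- lo + 1L
    if (lo > j - 1L) lo <- j - 1L          # adjacent-sample cut always qualifies
    rec <- NULL
    if (lo <= j - 1L) {
      for (i in lo:(j - 1L)) {
        if (!isred[i] && !isred[j]) next
        if (legacy) {
          mag <- abs(legacy_cv[i] - legacy_cv[j])
          ok <- mag > th$legacy_red_diff
        } else {
          ok <- !is.na(u[i]) && !is.na(u[j])
          mag <- if (ok) sqrt((u[i] - u[j])^2 + (v[i] - v[j])^2) else NA_real_
          ok <- ok && mag > th$red_uv_diff
        }
        if (!ok) next
        dir <- if (isred[j] && !isred[i]) 1
               else if (isred[i] && !isred[j]) -1
               else if (last_dir == 0) 1 else -last_dir
        if (last_dir != 0 && dir == last_dir) next   # alternation
        rec <- list(dir = dir, i = i, mag = mag)
        break
      }
    }
    if (!is.null(rec)) {
      out[[length(out) + 1L]] <- data.frame(
        kind = "red", direction = rec$dir,
        time = times[j], anchor_time = times[rec$i],
        span = times[j] - times[rec$i], magnitude = rec$mag,
        pre = NA_real_, post = NA_real_)
      anchor <- j
      last_dir <- rec$dir
    }
    j <- j + 1L
  }
  if (!length(out)) empty else do.call(rbind, out)
}

#' Merge fast flashes
#'
#' Runs of flashes whose same-direction leading edges are separated by 15 ms
#' or less (a rate of about 65 Hz or faster, which carries significantly
#' reduced risk) collapse to two transitions total — one per direction. The
#' merged pair is placed at the start or at the end of the run; the two
#' placements are alternative analyses and are never combined in one pass.
#'
#' @param trans ordered, alternating transition data.frame (one block or one
#'   aggregate event stream).
#' @param gap merge gap in seconds (default 0.015).
#' @param placement `"start"` or `"end"` of the run.
#' @return the transition data.frame with fast runs collapsed.
#' @export
fh_merge_fast_flashes <- function(trans, gap = 0.015,
                                  placement = c("start", "end")) {
  placement <- match.arg(placement)
  n <- nrow(trans)
  if (n < 3) return(trans)
  keep <- rep(TRUE, n)
  a <- 1L
  while (a <= n - 2L) {
    b <- a
    while (b + 2L <= n && trans$time[b + 2L] - trans$time[b] <= gap) b <- b + 2L
    # extend to include the trailing opposite-direction edge of the run
    if (b > a) {
      b2 <- min(b + 1L, n)
      drop <- setdiff(a:b2, if (placement == "start") c(a, a + 1L)
                            else c(b2 - 1L, b2))
      keep[drop] <- FALSE
      a <- b2 + 1L
    } else a <- a + 1L
  }
  trans[keep, , drop = FALSE]
}

# collision-resistant numeric row hash for series deduplication
.row_hash <- function(...) {
  mats <- list(...)
  n <- nrow(mats[[1]])
  h1 <- h2 <- numeric(n)
  for (m in mats) {
    if (anyNA(m)) m[is.na(m)] <- -777.777
    k <- ncol(m)
    w1 <- exp(seq(0.11, 1.31, length.out = k))
    w2 <- sqrt(seq(2.03, 17.07, length.out = k))
    h1 <- h1 + as.vector(m %*% w1)
    h2 <- h2 + as.vector(m %*% w2)
  }
  paste(signif(h1, 12), signif(h2, 12))
}

# Detect transitions for every block of a grid, deduplicating identical
# series (synthetic patterns have few distinct block waveforms). Returns a
# compact data.frame over unique series ids (`sid`) with an attribute
# `sid_blocks`: list mapping sid -> member block ids.
.grid_transitions <- function(grid, profile, units = "cd") {
  series <- switch(units, ire = grid$ire, grid$L_abs)
  key <- if (units == "ire") grid$hash_ire else grid$hash_cd
  if (is.null(key)) key <- .row_hash(series)
  uk <- which(!duplicated(key))
  map <- match(key, key[uk])
  lum <- lapply(seq_along(uk), function(s) {
    df <- fh_detect_luminance_transitions(series[uk[s], ], grid$times,
                                          profile, grid$env, units = units)
    if (nrow(df)) df$sid <- s
    df
  })

  ckey <- grid$hash_red
  if (is.null(ckey)) ckey <- .row_hash(grid$u, grid$v, grid$redfrac, grid$legacy_cv)
  cuk <- which(!duplicated(ckey))
  cmap <- match(ckey, ckey[cuk])
  nlum <- length(uk)
  red <- lapply(seq_along(cuk), function(s) {
    b <- cuk[s]
    df <- fh_detect_red_transitions(grid$u[b, ], grid$v[b, ], grid$redfrac[b, ],
                                    grid$legacy_cv[b, ], grid$times, profile)
    if (nrow(df)) df$sid <- nlum + s
    df
  })
  all <- c(lum, red)
  all <- all[vapply(all, nrow, 1L) > 0]
  sid_blocks <- c(split(seq_along(map), map),
                  lapply(split(seq_along(cmap), cmap), identity))
  names(sid_blocks) <- as.character(seq_len(nlum + length(cuk)))
  if (!length(all)) {
    out <- data.frame()
  } else {
    out <- do.call(rbind, all)
    out <- out[order(out$time, out$sid), , drop = FALSE]
  }
  attr(out, "sid_blocks") <- sid_blocks
  out
}
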