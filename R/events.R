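# Area aggregation: synchronicity merging and area-threshold evaluation.
#
# Per-block transitions that share kind and direction and whose leading edges
# fall within the synchronicity window (20 ms working value, a conservative
# 50 Hz flicker-fusion bound) are summed into one TransitionEvent. Events are
# then tested against the profile's area threshold: more than 25% of any
# 10-degree field (windowed mode, the 0.006 sr rule), or more than 25% of the
# screen (broadcast modes).

#' Merge synchronous per-block transitions into area events
#'
#' Greedy temporal clustering per kind and direction: an event absorbs every
#' same-direction transition whose leading edge lies within `sync_window` of
#' the event's earliest edge. Blocks are never double-counted within one
#' event.
#'
#' @param trans transition data.frame with a `block` column (from the
#'   per-block scans), time-ordered.
#' @param grid the `fh_grid` the transitions came from.
#' @param sync_window seconds, default 0.020.
#' @return data.frame of events: `kind`, `direction`, `time` (earliest
#'   member edge), `area_px2`, `n_blocks`, `magnitude` (area-weighted mean),
#'   `blocks` (list column).
#' @export
fh_merge_synchronous <- function(trans, grid, sync_window = 0.020) {
  if (!nrow(trans)) return(.empty_events())
  sid_blocks <- attr(trans, "sid_blocks")
  if (is.null(sid_blocks)) {           # plain per-block form: block id == sid
    trans$sid <- trans$block
    sid_blocks <- setNames(as.list(trans$block), as.character(trans$block))
  }
  sid_area <- vapply(sid_blocks, function(b) sum(grid$areas_px2[b]), 0)
  out <- vector("list", 0L)
  for (kd in split(trans, list(trans$kind, trans$direction), drop = TRUE)) {
    kd <- kd[order(kd$time), , drop = FALSE]
    taken <- rep(FALSE, nrow(kd))
    for (s in seq_len(nrow(kd))) {
      if (taken[s]) next
      cand <- which(!taken & kd$time >= kd$time[s] &
                    kd$time - kd$time[s] <= sync_window)
      # an area contributes once per event; its later same-direction
      # transitions seed further events (an area flashing twice inside
      # another's single flash stays two transitions)
      memb <- cand[!duplicated(kd$sid[cand])]
      taken[memb] <- TRUE
      sids <- kd$sid[memb]
      dupe <- rep(FALSE, length(sids))
      areas <- sid_area[as.character(sids)]
      blocks <- unique(unlist(sid_blocks[as.character(sids)], use.names = FALSE))
      mags <- kd$magnitude[memb][!dupe]
      pre <- kd$pre[memb][!dupe]; post <- kd$post[memb][!dupe]
      darker <- pmin(pre, post)
      mc <- ifelse(pre + post > 0, abs(post - pre) / (post + pre), 0)
      wmean <- function(x) if (all(is.na(x))) NA_real_
                           else sum(x * areas) / sum(areas)
      out[[length(out) + 1L]] <- data.frame(
        kind = kd$kind[1], direction = kd$direction[1],
        time = kd$time[s],
        area_px2 = sum(grid$areas_px2[blocks]),
        n_blocks = length(blocks),
        magnitude = wmean(mags),
        darker = wmean(darker),
        michelson = wmean(mc),
        blocks = I(list(blocks)))
    }
  }
  ev <- do.call(rbind, out)
  ev[order(ev$time, ev$kind), , drop = FALSE]
}

.empty_events <- function() {
  data.frame(kind = character(), direction = numeric(), time = numeric(),
             area_px2 = numeric(), n_blocks = integer(), magnitude = numeric(),
             darker = numeric(), michelson = numeric(), blocks = I(list()))
}

# circle/rectangle intersection area (window clipped to the frame); exact
# (pi r^2) when the window lies fully inside, strip-integrated otherwise.
.circle_rect_area <- function(cx, cy, r, w, h, nstrip = 512L) {
  if (cx - r >= 0 && cx + r <= w && cy - r >= 0 && cy + r <= h)
    return(pi * r^2)
  ys <- seq(max(0, cy - r), min(h, cy + r), length.out = nstrip + 1L)
  if (length(ys) < 2 || ys[1] >= ys[length(ys)]) return(0)
  mid <- (ys[-1] + ys[-length(ys)]) / 2
  dy <- diff(ys)
  half <- sqrt(pmax(r^2 - (mid - cy)^2, 0))
  x1 <- pmax(0, cx - half); x2 <- pmin(w, cx + half)
  sum(pmax(x2 - x1, 0) * dy)
}

# candidate window-center coordinates along one axis: the window stays
# on-screen when it fits (a mostly off-screen field sees less, not more);
# centered and clipped when it does not fit.
.window_centers <- function(extent, r, stride) {
  if (2 * r >= extent) return(extent / 2)
  cs <- seq(r, extent - r, by = stride)
  if (cs[length(cs)] < extent - r) cs <- c(cs, extent - r)
  cs
}

#' Evaluate the area threshold for events
#'
#' Windowed mode slides a circular 10-degree window over the frame (stride
#' 1/8 of the window diameter, plus a placement centered on each event's
#' member centroid) and takes the maximum of member-area-inside-window over
#' visible window area; hazardous when that fraction strictly exceeds 25%
#' (an area of exactly 0.006 sr is compliant). Screen mode compares the
#' summed area against 25% of the frame. NHK additionally classifies events
#' into moderate / intermediate / scene-change tiers (scene change: at least
#' 80% of the screen at intermediate-or-greater magnitude).
#'
#' @param events event data.frame from [fh_merge_synchronous()].
#' @param grid the `fh_grid`.
#' @param profile an `fh_profile`.
#' @param units magnitude units the events were detected in (`"cd"` or
#'   `"ire"`), used for NHK tier cuts.
#' @return events with added `screen_fraction`, `windowed_fraction`,
#'   `omega_sr`, `hazardous_area`, `nhk_class`.
#' @export
fh_evaluate_area <- function(events, grid, profile, units = "cd") {
  if (!nrow(events)) {
    for (cl in c("screen_fraction", "windowed_fraction", "omega_sr",
                 "hazardous_area", "nhk_class")) events[[cl]] <- numeric(0)
    return(events)
  }
  th <- profile$thresholds
  env <- grid$env
  frame_area <- grid$width * grid$height
  sr_per_px2 <- (env$px_angular_size * pi / 180)^2
  events$screen_fraction <- events$area_px2 / frame_area
  events$omega_sr <- events$area_px2 * sr_per_px2

  if (profile$area_mode == "windowed") {
    W <- fh_window_diameter_px(env, th$window_diameter_deg)
    r <- W / 2
    stride <- W / 8
    cx0 <- .window_centers(grid$width, r, stride)
    cy0 <- .window_centers(grid$height, r, stride)
    clamp <- function(x, extent) if (2 * r >= extent) extent / 2
                                 else min(max(x, r), extent - r)
    wf <- numeric(nrow(events))
    cache <- new.env(parent = emptyenv())
    ckey <- function(b) paste(length(b), min(b), max(b),
                              sum(as.numeric(b)), sum(as.numeric(b)^2))
    for (e in seq_len(nrow(events))) {
      blocks <- events$blocks[[e]]
      k <- ckey(blocks)
      if (!is.null(cache[[k]])) { wf[e] <- cache[[k]]; next }
      bc <- grid$centers[blocks, , drop = FALSE]
      ba <- grid$areas_px2[blocks]
      ctr <- c(sum(bc[, 1] * ba), sum(bc[, 2] * ba)) / sum(ba)
      cxs <- c(cx0, clamp(ctr[1], grid$width))
      cys <- c(cy0, clamp(ctr[2], grid$height))
      best <- 0
      for (cx in cxs) for (cy in cys) {
        inside <- (bc[, 1] - cx)^2 + (bc[, 2] - cy)^2 <= r^2
        num <- sum(ba[inside])
        if (num == 0) next
        den <- .circle_rect_area(cx, cy, r, grid$width, grid$height)
        if (den > 0) best <- max(best, num / den)
      }
      wf[e] <- min(best, 1)
      cache[[k]] <- wf[e]
    }
    events$windowed_fraction <- wf
    events$hazardous_area <- wf > th$area_fraction
  } else {
    events$windowed_fraction <- NA_real_
    events$hazardous_area <- events$screen_fraction > th$area_fraction
  }

  # NHK tier classification
  cls <- rep("none", nrow(events))
  if (isTRUE(th$nhk)) {
    mag <- events$magnitude
    if (units == "ire") {
      inter <- mag >= th$nhk_intermediate_ire
      moder <- mag >= th$nhk_moderate_ire[1] & mag < th$nhk_moderate_ire[2]
    } else {
      # HDR: cd/m^2 cuts below the 160 cd/m^2 darker state, Michelson above
      bright <- !is.na(events$darker) & events$darker >= th$dark_state_cut
      mc <- events$michelson
      inter <- ifelse(bright, mc > th$nhk_intermediate_mc,
                      mag >= th$nhk_intermediate_cd)
      moder <- ifelse(bright,
                      mc >= th$nhk_moderate_mc[1] & mc <= th$nhk_moderate_mc[2],
                      mag >= th$nhk_moderate_cd[1] & mag < th$nhk_moderate_cd[2])
      inter[is.na(inter)] <- FALSE; moder[is.na(moder)] <- FALSE
    }
    cls[moder] <- "moderate"
    cls[inter] <- "intermediate"
    scene <- inter & events$kind == "luminance" &
      events$screen_fraction >= th$nhk_scene_area
    cls[scene] <- "scene_change"
    # moderate-tier flashing counts from 25% of screen regardless of class
    events$hazardous_area <- events$screen_fraction > th$area_fraction
  }
  events$nhk_class <- cls
  events
}
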