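# Guideline conformance profiles.
#
# Every comparison the analyzer makes is driven by a named, versioned
# threshold set. One profile per international guideline plus the harmonized
# proposed provision. All numbers are overridable; overrides are echoed into
# the report for provenance.

.PROFILE_IDS <- c("proposed", "wcag2x", "wcag20_legacy_red", "iso9241_391",
                  "itu_bt1702", "ofcom", "nhk_jba")

#' Guideline profile
#'
#' Builds the threshold set for one guideline. Defaults:
#'
#' * luminance: transitions count when the states differ by >= 20 cd/m^2 and
#'   the darker state is < 160 cd/m^2, or (HDR-capable profiles) when the
#'   darker state is >= 160 cd/m^2 and the Michelson contrast is >= 1/17.
#' * red: a saturated-red state (linear R/(R+G+B) >= 0.8) and a state whose
#'   u'v' chromaticity differs by more than 0.2; the legacy WCAG 2.0/2.1 mode
#'   instead requires legacy critical values differing by more than 20.
#' * rate: more than 3 flashes (6 alternating transitions) in any 1 s window.
#' * area: 25% of any 10-degree field (windowed) or 25% of the screen.
#' * timing (proposed provision): 66 ms qualifying duration, 20 ms
#'   synchronicity window, 15 ms fast-flash merge gap.
#'
#' Profile-specific differences: `ofcom`/`itu_bt1702` carry the leading-edge
#' spacing exception (334 ms at 60 Hz, 360 ms at 50 Hz); `nhk_jba` carries the
#' moderate/intermediate/scene-change tiers; `wcag2x`/`wcag20_legacy_red` use
#' the windowed area mode and relative-luminance gating; the broadcast
#' profiles use 25%-of-screen.
#'
#' @param id profile identifier: `"proposed"`, `"wcag2x"`,
#'   `"wcag20_legacy_red"`, `"iso9241_391"`, `"itu_bt1702"`, `"ofcom"`, or
#'   `"nhk_jba"`.
#' @param ... named threshold overrides (recorded in `$overrides`).
#' @return an object of class `fh_profile`.
#' @export
fh_profile <- function(id = .PROFILE_IDS, ...) {
  id <- match.arg(id)
  th <- list(
    luminance_diff = 20,        # cd/m^2, >= counts
    dark_state_cut = 160,       # cd/m^2
    bright_state_contrast = 1 / 17,
    wcag_rel_diff = 0.1,        # relative-luminance mode
    wcag_dark_cut = 0.8,
    red_sat_cut = 0.8,
    red_uv_diff = 0.2,          # strictly 'more than'
    legacy_red_diff = 20,       # strictly 'more than'
    qualifying_duration = 0.066,
    sync_window = 0.020,
    fast_flash_gap = 0.015,
    flashes_per_s = 3,          # violation when count/2 exceeds this
    area_fraction = 0.25,       # strictly 'more than'
    window_diameter_deg = 10,
    hazard_solid_angle_sr = 0.006,
    spacing_exception = FALSE,
    spacing_bound = 0.334,      # 60 Hz environment; 0.360 for 50 Hz
    legacy_red = FALSE,
    nhk = FALSE,
    # NHK tiers: SDR in IRE percent of encoded signal, HDR in cd/m^2/contrast
    nhk_moderate_ire = c(10, 20), nhk_intermediate_ire = 20,
    nhk_moderate_cd = c(20, 40), nhk_intermediate_cd = 40,
    nhk_moderate_mc = c(1 / 17, 1 / 9), nhk_intermediate_mc = 1 / 9,
    nhk_moderate_rate = 5, nhk_moderate_cap_s = 2,
    nhk_scene_rate = 1.5, nhk_scene_area = 0.80,
    # extended-failure heuristic (non-normative; see vignette)
    extended_window_s = 5, extended_frame_frac = 0.8,
    extended_factor = 0.8, extended_min_rate = 2,
    fast_merge = FALSE
  )
  area_mode <- "windowed"
  hdr_contrast <- FALSE
  if (id == "proposed") {
    th$fast_merge <- TRUE
    hdr_contrast <- TRUE
  } else if (id %in% c("wcag2x", "wcag20_legacy_red")) {
    th$legacy_red <- id == "wcag20_legacy_red"
  } else if (id == "iso9241_391") {
    area_mode <- "screen"
  } else if (id == "itu_bt1702") {
    area_mode <- "screen"
    th$spacing_exception <- TRUE
    hdr_contrast <- TRUE
  } else if (id == "ofcom") {
    area_mode <- "screen"
    th$spacing_exception <- TRUE
  } else if (id == "nhk_jba") {
    area_mode <- "screen"
    th$nhk <- TRUE
    hdr_contrast <- TRUE
  }
  ov <- list(...)
  bad <- setdiff(names(ov), names(th))
  if (length(bad)) stop("unknown threshold override(s): ", paste(bad, collapse = ", "))
  th[names(ov)] <- ov
  structure(list(id = id, thresholds = th, area_mode = area_mode,
                 hdr_contrast = hdr_contrast, overrides = ov),
            class = "fh_profile")
}

#' All guideline profiles
#' @return named list of the seven default profiles.
#' @export
fh_all_profiles <- function() {
  setNames(lapply(.PROFILE_IDS, fh_profile), .PROFILE_IDS)
}

#' @export
print.fh_profile <- function(x, ...) {
  cat("<fh_profile>", x$id, "| area:", x$area_mode,
      if (length(x$overrides)) paste0("| overrides: ",
        paste(names(x$overrides), collapse = ", ")) else "", "\n")
  invisible(x)
}
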