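# Viewing-field geometry: angle/pixel/steradian conversions and environments.
#
# In-frame window math uses the small-angle planar convention (pixels
# proportional to visual angle), matching CSS-pixel practice; exact cone and
# chord formulas are used for whole-field conversions. The two published
# convenience constants for the 10-degree field follow different derivations
# (470 px is the exact chord at the CSS reference geometry, 416 px the
# small-angle equal-area square); both functions below reproduce their own
# constant. See the methods vignette.

#' Viewing environment
#'
#' Describes the geometry and luminance of the assumed display. Exactly one of
#' `px_angular_size` (degrees subtended per pixel) or physical dimensions plus
#' viewing distance must be given.
#'
#' @param width_px,height_px frame dimensions in pixels.
#' @param px_angular_size degrees of visual angle per pixel (CSS reference
#'   pixel: 0.0213).
#' @param screen_width,screen_height,distance physical dimensions and viewing
#'   distance, any single common unit; used to derive `px_angular_size`.
#' @param reference_luminance cd/m^2 of reference white (200 typical indoor,
#'   48 theater).
#' @param area_mode `"windowed"` (0.006 sr within any 10-degree field) or
#'   `"screen"` (25% of the screen).
#' @return an object of class `fh_env`.
#' @export
fh_env <- function(width_px = 1920, height_px = 1080,
                   px_angular_size = NULL,
                   screen_width = NULL, screen_height = NULL, distance = NULL,
                   reference_luminance = 200,
                   area_mode = c("windowed", "screen")) {
  area_mode <- match.arg(area_mode)
  phys <- !is.null(screen_width) && !is.null(screen_height) && !is.null(distance)
  if (is.null(px_angular_size) && !phys)
    stop("give either px_angular_size or physical dimensions + distance")
  if (!is.null(px_angular_size) && phys)
    stop("give only one of px_angular_size or physical dimensions + distance")
  if (phys) {
    stopifnot(screen_width > 0, screen_height > 0, distance > 0)
    # small-angle per-pixel subtense at screen center
    px_angular_size <- (screen_width / width_px / distance) * 180 / pi
  }
  stopifnot(px_angular_size > 0, width_px > 0, height_px > 0,
            reference_luminance > 0)
  # viewing distance expressed in pixel units (for exact chord conversions)
  dist_px <- if (phys) distance / (screen_width / width_px)
             else 1 / tan(px_angular_size * pi / 180)
  structure(list(
    width_px = width_px, height_px = height_px,
    px_angular_size = px_angular_size,
    distance_px = dist_px,
    physical = phys,
    screen_width = screen_width, screen_height = screen_height,
    distance = distance,
    reference_luminance = reference_luminance,
    area_mode = area_mode), class = "fh_env")
}

#' Preset viewing environments
#'
#' * `"css-reference"`: 1920x1080, CSS reference pixels (0.0213 deg/px, i.e.
#'   a Full HD screen at 28 in / 71.1 cm), reference white 200 cd/m^2,
#'   windowed 10-degree-field area threshold.
#' * `"tv-unknown"`: television of unknown size; 25%-of-screen area mode.
#' * `"theater"`: dark-adapted cinema, reference white 48 cd/m^2.
#'
#' @param name preset name.
#' @param ... overrides passed to [fh_env()] fields.
#' @return an `fh_env`.
#' @export
fh_env_preset <- function(name = c("css-reference", "tv-unknown", "theater"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "css-reference" = fh_env(1920, 1080, px_angular_size = 0.0213),
    "tv-unknown"    = fh_env(1920, 1080, px_angular_size = 0.0213,
                             area_mode = "screen"),
    "theater"       = fh_env(1920, 1080, px_angular_size = 0.0213,
                             reference_luminance = 48))
  # CSS reference geometry: the chord distance is 96 px/in at 28 in
  base$distance_px <- 96 * 28
  ov <- list(...)
  for (nm in names(ov)) base[[nm]] <- ov[[nm]]
  base
}

#' Convert a visual angle to pixels
#'
#' Small-angle planar conversion: `angle / px_angular_size`. Linear in the
#' angle; under the CSS reference pixel, 0.0213 degrees maps to one pixel.
#'
#' @param angle_deg visual angle in degrees.
#' @param env an `fh_env`.
#' @return extent in pixels (unrounded).
#' @export
fh_degrees_to_px <- function(angle_deg, env) {
  stopifnot(inherits(env, "fh_env"), all(angle_deg >= 0))
  angle_deg / env$px_angular_size
}

#' Diameter in pixels of an analysis window of given angular diameter
#'
#' Exact chord at the environment's viewing distance:
#' `2 * distance_px * tan(theta/2)`. At the CSS reference geometry this gives
#' the published 470 px for the 10-degree field (and 235 px for the 0.006 sr
#' disc).
#'
#' @param env an `fh_env`.
#' @param angle_deg angular diameter, default 10.
#' @return diameter in pixels (unrounded).
#' @export
fh_window_diameter_px <- function(env, angle_deg = 10) {
  stopifnot(inherits(env, "fh_env"), angle_deg >= 0)
  2 * env$distance_px * tan(angle_deg / 2 * pi / 180)
}

#' Full cone angle of a given solid angle
#'
#' Inverts `omega = 2*pi*(1 - cos(theta/2))`. 0.006 sr corresponds to a cone
#' of about 5.007 degrees, a 235 px disc under CSS reference pixels.
#'
#' @param omega_sr solid angle in steradians, in \[0, 2*pi).
#' @return full cone angle theta in degrees.
#' @export
fh_solid_angle_to_cone_diameter <- function(omega_sr) {
  stopifnot(all(omega_sr >= 0), all(omega_sr < 2 * pi))
  2 * acos(1 - omega_sr / (2 * pi)) * 180 / pi
}

#' Solid angle of a cone of given full angle
#' @param theta_deg full cone angle in degrees.
#' @return solid angle in steradians.
#' @export
fh_cone_solid_angle <- function(theta_deg) {
  2 * pi * (1 - cos(theta_deg / 2 * pi / 180))
}

#' Side of the square with the same area as a circular window
#'
#' `side = diameter * sqrt(pi)/2` in the small-angle pixel metric. For the
#' 10-degree window under CSS reference pixels this is the published 416 px
#' convenience square.
#'
#' @param window_diameter_deg angular diameter of the circular window.
#' @param env an `fh_env`.
#' @return side length in pixels (unrounded).
#' @export
fh_equal_area_square_side <- function(window_diameter_deg, env) {
  fh_degrees_to_px(window_diameter_deg, env) * sqrt(pi) / 2
}

#' Solid angle subtended by the whole screen
#'
#' Exact on-axis rectangle formula
#' `Omega = 4*atan(a*b / (2*d*sqrt(4*d^2 + a^2 + b^2)))` when physical
#' dimensions are known; otherwise the rectangle formula applied at the
#' pixel-unit viewing distance. Also reports the screen fraction that 0.006 sr
#' represents.
#'
#' @param env an `fh_env`.
#' @return list with `omega_sr` and `fraction_0p006`.
#' @export
fh_screen_solid_angle <- function(env) {
  stopifnot(inherits(env, "fh_env"))
  if (env$physical) {
    a <- env$screen_width; b <- env$screen_height; d <- env$distance
  } else {
    a <- env$width_px; b <- env$height_px; d <- env$distance_px
  }
  if (a <= 0 || b <= 0) return(list(omega_sr = 0, fraction_0p006 = NA_real_))
  omega <- 4 * atan(a * b / (2 * d * sqrt(4 * d^2 + a^2 + b^2)))
  list(omega_sr = omega, fraction_0p006 = 0.006 / omega)
}
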