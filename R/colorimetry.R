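# Transfer functions, luminance, chromaticity and red-flash scoring.
#
# All hazard math downstream works on *linear* light. Encoded code values are
# expanded with the transfer function of the declared space, luminance is
# weighted with the primaries' Y row, and chromaticity goes through CIE XYZ to
# the 1976 UCS (u', v') plane.

# sRGB / BT.709 D65 RGB -> XYZ matrix (IEC 61966-2-1 primaries, D65 white).
.M_SRGB <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
# normalize so the Y row sums to exactly 1 (white -> Y = 1); chromaticity is
# scale invariant and unaffected
.M_SRGB <- .M_SRGB / sum(.M_SRGB[2, ])

# BT.2020 primaries, D65 white.
.M_2020 <- matrix(c(
  0.6369580, 0.1446169, 0.1688810,
  0.2627002, 0.6779981, 0.0593017,
  0.0000000, 0.0280727, 1.0609851), 3, 3, byrow = TRUE)
.M_2020 <- .M_2020 / sum(.M_2020[2, ])

.SPACES <- c("sRGB", "BT.1886", "BT.2020-SDR", "PQ", "HLG")

.space_matrix <- function(space) {
  switch(space,
    "sRGB"    = .M_SRGB,
    "BT.1886" = .M_SRGB,      # BT.709 primaries
    "BT.2020-SDR" = .M_2020,
    "PQ" = .M_2020, "HLG" = .M_2020,
    stop("unsupported color space tag: ", space))
}

#' Luminance weights (Y row) for a color space's primaries
#' @param space color space tag.
#' @return numeric length-3 vector of linear-RGB luminance weights.
#' @keywords internal
.space_luma_weights <- function(space) .space_matrix(space)[2, ]

#' Encoded color
#'
#' A small record of code values plus a color-space tag. Code values may be
#' given as 8-bit integers (0--255) or as normalized codes in \[0, 1\].
#'
#' @param r8,g8,b8 code values, all on the same scale.
#' @param space one of `"sRGB"`, `"BT.1886"`, `"BT.2020-SDR"`, `"PQ"`, `"HLG"`.
#' @param bits bit depth when integer codes are supplied (default 8).
#' @return an object of class `fh_encoded` holding normalized codes in \[0,1\].
#' @export
fh_encoded <- function(r8, g8, b8, space = "sRGB", bits = 8L) {
  space <- match.arg(space, .SPACES)
  v <- c(r8, g8, b8)
  maxcode <- 2^bits - 1
  if (any(v > 1)) v <- v / maxcode
  if (any(v < 0 | v > 1)) stop("code values out of range for declared bit depth")
  structure(list(codes = v, space = space), class = "fh_encoded")
}

#' Parse an sRGB hex color
#' @param hex string like `"#FF8800"`.
#' @return an `fh_encoded` sRGB color.
#' @export
fh_hex <- function(hex) {
  stopifnot(grepl("^#?[0-9a-fA-F]{6}$", hex))
  hex <- sub("^#", "", hex)
  v <- strtoi(substring(hex, c(1, 3, 5), c(2, 4, 6)), 16L)
  fh_encoded(v[1], v[2], v[3], space = "sRGB")
}

# Piecewise sRGB electro-optical expansion, vectorised over codes in [0,1].
.srgb_expand <- function(u) ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
.srgb_compress <- function(L) ifelse(L <= 0.0031308, 12.92 * L, 1.055 * L^(1 / 2.4) - 0.055)

# SMPTE ST 2084 / BT.2100 PQ EOTF: encoded [0,1] -> absolute cd/m^2.
.pq_m1 <- 2610 / 16384; .pq_m2 <- 2523 / 4096 * 128
.pq_c1 <- 3424 / 4096;  .pq_c2 <- 2413 / 4096 * 32; .pq_c3 <- 2392 / 4096 * 32
.pq_eotf <- function(u) {
  p <- pmax(u, 0)^(1 / .pq_m2)
  10000 * (pmax(p - .pq_c1, 0) / (.pq_c2 - .pq_c3 * p))^(1 / .pq_m1)
}

# BT.2100 HLG inverse OETF: encoded [0,1] -> scene-linear [0,1].
.hlg_a <- 0.17883277; .hlg_b <- 0.28466892; .hlg_c <- 0.55991073
.hlg_inv_oetf <- function(u) {
  ifelse(u <= 0.5, u^2 / 3, (exp((u - .hlg_c) / .hlg_a) + .hlg_b) / 12)
}

#' Linearize an encoded color
#'
#' Expands code values to normalized linear light using the transfer function
#' of the declared space: the IEC 61966-2-1 piecewise curve for sRGB, the
#' BT.1886 EOTF (pure 2.4 power with black at zero) for SDR television spaces,
#' and the BT.2100 PQ/HLG curves for HDR tags (normalized to their nominal
#' peaks of 10,000 and 1,000 cd/m^2 respectively).
#'
#' @param c an `fh_encoded` color.
#' @return an `fh_linear` color: list with `rgb` (linear, \[0,1\] for SDR) and
#'   `space`.
#' @export
fh_linearize <- function(c) {
  stopifnot(inherits(c, "fh_encoded"))
  u <- c$codes
  rgb <- switch(c$space,
    "sRGB" = .srgb_expand(u),
    "BT.1886" = , "BT.2020-SDR" = u^2.4,
    "PQ"  = .pq_eotf(u) / 10000,
    "HLG" = .hlg_inv_oetf(u))
  structure(list(rgb = rgb, space = c$space), class = "fh_linear")
}

#' Relative luminance of a linear color
#'
#' Y of CIE XYZ, in \[0,1\] for SDR content, from the declared primaries'
#' luminance weights (BT.709 weights for sRGB/BT.1886).
#'
#' @param c an `fh_linear` color.
#' @return relative luminance.
#' @export
fh_relative_luminance <- function(c) {
  stopifnot(inherits(c, "fh_linear"))
  sum(.space_luma_weights(c$space) * c$rgb)
}

#' Absolute display luminance
#'
#' Maps relative luminance (or a PQ/HLG encoded code) to cd/m^2. SDR spaces
#' scale by the environment's reference luminance (default 200 cd/m^2; 48 for
#' the theater preset). PQ decodes absolutely to a 10,000 cd/m^2 peak; HLG is
#' rendered with the BT.2100 OOTF at a 1,000 cd/m^2 nominal peak (system
#' gamma 1.2).
#'
#' @param y relative luminance for SDR spaces, or the encoded signal in \[0,1\]
#'   for PQ; for HLG pass scene-linear luminance.
#' @param space color space tag.
#' @param reference_luminance cd/m^2 reference white for SDR spaces.
#' @return luminance in cd/m^2.
#' @export
fh_absolute_luminance <- function(y, space = "sRGB", reference_luminance = 200) {
  space <- match.arg(space, .SPACES)
  if (space %in% c("sRGB", "BT.1886", "BT.2020-SDR")) {
    if (!is.finite(reference_luminance) || reference_luminance <= 0)
      stop("SDR content needs a positive reference luminance")
    return(y * reference_luminance)
  }
  if (space == "PQ") return(.pq_eotf(y))
  1000 * pmax(y, 0)^1.2                  # HLG display light at nominal peak
}

#' Michelson contrast between two luminance states
#'
#' (L_high - L_low) / (L_high + L_low). Arguments may be given in either
#' order; scale invariant; defined as 0 when both states are black.
#'
#' @param l1,l2 non-negative luminances (any common unit).
#' @return contrast in \[0, 1).
#' @export
fh_michelson <- function(l1, l2) {
  stopifnot(all(l1 >= 0), all(l2 >= 0))
  hi <- pmax(l1, l2); lo <- pmin(l1, l2)
  s <- hi + lo
  ifelse(s == 0, 0, (hi - lo) / s)
}

#' Saturated-red fraction
#'
#' R / (R + G + B) on linear channels. A color is saturated red when the
#' fraction is >= 0.8. Black (zero-sum) has an undefined fraction and is never
#' saturated red: a red transition therefore requires a non-black red state.
#'
#' @param c an `fh_linear` color.
#' @return the fraction in \[0,1\], or `NA_real_` for black.
#' @export
fh_red_fraction <- function(c) {
  stopifnot(inherits(c, "fh_linear"))
  s <- sum(c$rgb)
  if (s <= 0) return(NA_real_)
  c$rgb[1] / s
}

#' Legacy WCAG 2.0 red critical value
#'
#' max(0, (R - G - B)) * 320 on linear channels. Two states form a legacy red
#' transition when their critical values differ by more than 20.
#'
#' @param c an `fh_linear` color.
#' @return critical value >= 0.
#' @export
fh_wcag20_critical_value <- function(c) {
  stopifnot(inherits(c, "fh_linear"))
  max(0, c$rgb[1] - c$rgb[2] - c$rgb[3]) * 320
}

#' CIE 1976 UCS chromaticity of a linear color
#'
#' Linear RGB -> XYZ via the declared primaries, then
#' u' = 4X/(X+15Y+3Z), v' = 9Y/(X+15Y+3Z). Chromaticity is undefined for
#' black, and invariant under positive scaling of the color.
#'
#' @param c an `fh_linear` color.
#' @return list with `u`, `v` and logical `defined`.
#' @export
fh_chromaticity <- function(c) {
  stopifnot(inherits(c, "fh_linear"))
  if (sum(c$rgb) <= 0)
    return(list(u = NA_real_, v = NA_real_, defined = FALSE))
  xyz <- as.vector(.space_matrix(c$space) %*% c$rgb)
  d <- xyz[1] + 15 * xyz[2] + 3 * xyz[3]
  list(u = 4 * xyz[1] / d, v = 9 * xyz[2] / d, defined = TRUE)
}

#' Euclidean distance on the u'v' plane
#' @param a,b chromaticities from [fh_chromaticity()].
#' @return distance >= 0.
#' @export
fh_uv_distance <- function(a, b) {
  if (!isTRUE(a$defined) || !isTRUE(b$defined))
    stop("cannot compare undefined chromaticities (black states)")
  sqrt((a$u - b$u)^2 + (a$v - b$v)^2)
}

# --- vectorised frame-level helpers (arrays of linear RGB) -------------------

# XYZ planes from H x W x 3 linear array.
.xyz_planes <- function(lin, space) {
  M <- .space_matrix(space)
  list(X = M[1, 1] * lin[, , 1] + M[1, 2] * lin[, , 2] + M[1, 3] * lin[, , 3],
       Y = M[2, 1] * lin[, , 1] + M[2, 2] * lin[, , 2] + M[2, 3] * lin[, , 3],
       Z = M[3, 1] * lin[, , 1] + M[3, 2] * lin[, , 2] + M[3, 3] * lin[, , 3])
}
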