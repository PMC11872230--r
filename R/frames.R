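# Frame sequences and the analysis grid.
#
# Frames are decoded to per-block time series of *linear* quantities before
# any hazard rule is applied. Averaging over blocks no larger than 0.1 degrees
# of visual angle is what makes the fine-pattern / white-noise exception
# emerge by construction: a balanced checkerboard of sub-0.1-degree cells
# averages to a constant block luminance and produces no transitions.

#' Frame sequence
#'
#' @param frames list of H x W x 3 numeric arrays of *encoded* code values in
#'   \[0,1\] (a single frame may be passed directly).
#' @param fps constant frame rate; ignored if `timestamps` given.
#' @param timestamps per-frame presentation times in seconds, strictly
#'   increasing.
#' @param space color space tag (see [fh_encoded()]).
#' @return an object of class `fh_frames`.
#' @export
fh_frames <- function(frames, fps = NULL, timestamps = NULL, space = "sRGB") {
  space <- match.arg(space, .SPACES)
  if (is.array(frames) && length(dim(frames)) == 3) frames <- list(frames)
  if (length(frames) == 0) stop("empty frame sequence")
  dims <- vapply(frames, function(f) dim(f)[1:2], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frame dimensions change mid-stream")
  if (is.null(timestamps)) {
    if (is.null(fps) || fps <= 0) stop("need fps or timestamps")
    timestamps <- (seq_along(frames) - 1) / fps
  }
  if (length(timestamps) != length(frames) ||
      any(diff(timestamps) <= 0))
    stop("timestamps must match frames and be strictly increasing")
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 1 + 1e-9)
    stop("encoded code values must lie in [0, 1]")
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 fps = fps, space = space,
                 height = dims[1, 1], width = dims[2, 1]),
            class = "fh_frames")
}

#' @export
print.fh_frames <- function(x, ...) {
  cat(sprintf("<fh_frames> %d frames %dx%d [%s], %.3f s\n",
              length(x$frames), x$width, x$height, x$space,
              diff(range(x$timestamps))))
  invisible(x)
}

#' Default analysis block size
#'
#' Largest integer pixel size whose angular subtense does not exceed
#' 0.1 degrees (6 arcmin) in the given environment, minimum 1 px.
#'
#' @param env an `fh_env`.
#' @param max_block_deg angular ceiling, default 0.1.
#' @return block side length in pixels.
#' @export
fh_default_block_px <- function(env, max_block_deg = 0.1) {
  max(1L, floor(max_block_deg / env$px_angular_size))
}

# Mean over b x b blocks of an H x W matrix using a precomputed group index.
.block_index <- function(h, w, b) {
  by <- (seq_len(h) - 1L) %/% b
  bx <- (seq_len(w) - 1L) %/% b
  nby <- max(by) + 1L
  idx <- rep(bx * nby, each = h) + rep(by, w) + 1L
  list(idx = idx, nby = nby, nbx = max(bx) + 1L,
       counts = tabulate(idx, nbins = nby * (max(bx) + 1L)))
}

#' Build the per-block analysis grid
#'
#' Converts a frame sequence into per-block time series: block means of
#' linear RGB (averaged in linear light), from which absolute luminance,
#' chromaticity, saturated-red fraction and (for NHK SDR analysis) encoded
#' signal percent are derived. Partial edge blocks carry their true pixel
#' area.
#'
#' @param fs an `fh_frames`.
#' @param env an `fh_env`.
#' @param block_px block side in pixels; default [fh_default_block_px()].
#' @return an object of class `fh_grid` with matrices (blocks x frames)
#'   `L_abs`, `Y_rel`, `u`, `v`, `defined`, `redfrac`, `ire`, block metadata
#'   (`areas_px2`, `centers`), `times`, `env`.
#' @export
fh_build_grid <- function(fs, env, block_px = NULL) {
  stopifnot(inherits(fs, "fh_frames"), inherits(env, "fh_env"))
  if (is.null(block_px)) block_px <- fh_default_block_px(env)
  stopifnot(block_px >= 1)
  h <- fs$height; w <- fs$width
  bi <- .block_index(h, w, block_px)
  nb <- bi$nby * bi$nbx
  nf <- length(fs$frames)
  space <- fs$space
  wts <- .space_luma_weights(space)
  M <- .space_matrix(space)

  R <- G <- B <- IRE <- matrix(0, nb, nf)
  for (k in seq_len(nf)) {
    fr <- fs$frames[[k]]
    enc <- matrix(fr, h * w, 3)
    lin <- switch(space,
      "sRGB" = .srgb_expand(enc),
      "BT.1886" = , "BT.2020-SDR" = enc^2.4,
      "PQ" = .pq_eotf(enc) / 10000,
      "HLG" = .hlg_inv_oetf(enc))
    R[, k] <- rowsum(lin[, 1], bi$idx) / bi$counts
    G[, k] <- rowsum(lin[, 2], bi$idx) / bi$counts
    B[, k] <- rowsum(lin[, 3], bi$idx) / bi$counts
    # encoded-domain luma percent, for the NHK SDR (IRE) tiers
    IRE[, k] <- 100 * rowsum(enc %*% wts, bi$idx)[, 1] / bi$counts
  }
  Y <- wts[1] * R + wts[2] * G + wts[3] * B
  L <- switch(space,
    "PQ"  = Y * 10000,
    "HLG" = 1000 * pmax(Y, 0)^1.2,
    Y * env$reference_luminance)
  X <- M[1, 1] * R + M[1, 2] * G + M[1, 3] * B
  Z <- M[3, 1] * R + M[3, 2] * G + M[3, 3] * B
  s <- R + G + B
  defined <- s > 0
  den <- X + 15 * Y + 3 * Z
  u <- 4 * X / den; v <- 9 * Y / den; redfrac <- R / s
  if (!all(defined)) u[!defined] <- v[!defined] <- redfrac[!defined] <- NA_real_
  legacy_cv <- pmax(R - G - B, 0) * 320    # pmax keeps dims of its first arg

  # block centers (px, x right / y down) and true pixel areas
  centers_y <- (pmin(seq_len(bi$nby) * block_px, h) +
                (seq_len(bi$nby) - 1) * block_px) / 2
  centers_x <- (pmin(seq_len(bi$nbx) * block_px, w) +
                (seq_len(bi$nbx) - 1) * block_px) / 2
  centers <- cbind(x = rep(centers_x, each = bi$nby),
                   y = rep(centers_y, bi$nbx))

  structure(list(
    L_abs = L, Y_rel = Y, u = u, v = v, defined = defined,
    redfrac = redfrac, legacy_cv = legacy_cv, ire = IRE,
    hash_cd = .row_hash(L), hash_ire = .row_hash(IRE),
    hash_red = .row_hash(u, v, redfrac, legacy_cv),
    areas_px2 = bi$counts, centers = centers,
    block_px = block_px, nbx = bi$nbx, nby = bi$nby,
    width = w, height = h,
    times = fs$timestamps, space = space, env = env),
    class = "fh_grid")
}

#' @export
print.fh_grid <- function(x, ...) {
  cat(sprintf("<fh_grid> %d blocks (%d px) x %d frames\n",
              nrow(x$L_abs), x$block_px, ncol(x$L_abs)))
  invisible(x)
}
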