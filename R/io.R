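# Input decoding, configuration and report serialization.
#
# Lossless inputs only: PNG (and optionally TIFF) image sequences, raw
# planar float dumps for bit-exact tests, or in-memory frame lists. Frame
# timing comes from a sidecar (fps or per-frame timestamps) or from the
# call. Reports serialize to versioned JSON and optional per-violation CSV.

REPORT_SCHEMA_VERSION <- "1.0"

#' Read a frame sequence from disk
#'
#' Accepts a directory of numbered `.png` (or `.tif`/`.tiff`) frames, with an
#' optional `timing.json` sidecar (`{"fps": 30}` or `{"timestamps": [...]}`
#' plus optional `"space"`), or a single raw planar dump written by
#' [fh_write_raw()].
#'
#' @param path directory of frames or a `.raw` file.
#' @param fps frame rate override (required if no sidecar).
#' @param space color space override.
#' @return an `fh_frames`.
#' @export
fh_read_input <- function(path, fps = NULL, space = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no frames found in ", path)
    timestamps <- NULL
    sidecar <- file.path(path, "timing.json")
    if (file.exists(sidecar)) {
      tj <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (!is.null(tj$fps) && is.null(fps)) fps <- tj$fps
      if (!is.null(tj$timestamps)) timestamps <- tj$timestamps
      if (!is.null(tj$space) && is.null(space)) space <- tj$space
    }
    if (is.null(fps) && is.null(timestamps))
      stop("no frame timing: give fps or provide a timing.json sidecar (", path, ")")
    if (is.null(space)) {
      space <- "sRGB"
      message("no color-space metadata for ", path, "; assuming sRGB")
    }
    frames <- lapply(files, function(f) {
      img <- if (grepl("png$", f, ignore.case = TRUE)) png::readPNG(f)
      else if (requireNamespace("tiff", quietly = TRUE)) tiff::readTIFF(f)
      else stop("TIFF input requires the 'tiff' package: ", f)
      if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
      img[, , 1:3, drop = FALSE]
    })
    fh_frames(frames, fps = fps, timestamps = timestamps, space = space)
  } else if (file.exists(path)) {
    .read_raw(path, space = space)
  } else stop("input not found: ", path)
}

#' Write frames as a raw planar dump
#'
#' Little-endian float64, header: int32 c(height, width, channels, n_frames),
#' then per frame the channel planes in column-major order, then the
#' timestamps. Bit-exact round trip.
#'
#' @param fs an `fh_frames`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
fh_write_raw <- function(fs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(fs$height, fs$width, 3L, length(fs$frames))), con,
           size = 4, endian = "little")
  for (f in fs$frames) writeBin(as.vector(f), con, size = 8, endian = "little")
  writeBin(fs$timestamps, con, size = 8, endian = "little")
  invisible(path)
}

.read_raw <- function(path, space = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", 4, size = 4, endian = "little")
  h <- hdr[1]; w <- hdr[2]; nc <- hdr[3]; nf <- hdr[4]
  if (nc != 3 || nf < 1) stop("corrupt raw dump: ", path)
  frames <- lapply(seq_len(nf), function(k)
    array(readBin(con, "double", h * w * nc, size = 8, endian = "little"),
          c(h, w, nc)))
  ts <- readBin(con, "double", nf, size = 8, endian = "little")
  fh_frames(frames, timestamps = ts, space = if (is.null(space)) "sRGB" else space)
}

#' Write a fixture (PNG sequence + sidecar + ground-truth manifest entry)
#'
#' @param gen output of [fh_generate()].
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
fh_write_fixture <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fs <- gen$frames
  for (k in seq_along(fs$frames))
    png::writePNG(fs$frames[[k]], file.path(dir, sprintf("frame_%04d.png", k)))
  jsonlite::write_json(
    list(timestamps = fs$timestamps, space = fs$space),
    file.path(dir, "timing.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(pattern = gen$spec$pattern,
         expected_violation = as.list(gen$truth$expected_violation),
         expected_transitions = gen$truth$expected_transitions,
         screen_fraction = gen$truth$screen_fraction),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# report -> plain list for serialization
.report_as_list <- function(report) {
  res <- lapply(report$results, function(r) {
    ev <- r$events
    ev$blocks <- NULL
    list(profile = r$profile$id,
         overrides = r$profile$overrides,
         pass = r$pass,
         events = ev,
         violations = r$violations,
         warnings = r$warnings)
  })
  list(schema_version = REPORT_SCHEMA_VERSION,
       tool = list(name = "flashhazard",
                   version = as.character(utils::packageVersion("flashhazard"))),
       input = report$input,
       environment = list(
         width_px = report$env$width_px, height_px = report$env$height_px,
         px_angular_size = report$env$px_angular_size,
         reference_luminance = report$env$reference_luminance,
         area_mode = report$env$area_mode),
       block_px = report$block_px,
       results = res)
}

#' Write an analysis report
#'
#' JSON always; CSV (one row per violation) when `csv` is given. Output is
#' byte-deterministic for identical input and configuration.
#'
#' @param report an `fh_report` from [fh_analyze()].
#' @param json path for the JSON report.
#' @param csv optional path for the per-violation CSV.
#' @return named list of the files written, invisibly.
#' @export
fh_write_report <- function(report, json, csv = NULL) {
  stopifnot(inherits(report, "fh_report"))
  jsonlite::write_json(.report_as_list(report), json, auto_unbox = TRUE,
                       digits = NA, null = "null")
  out <- list(json = json)
  if (!is.null(csv)) {
    v <- do.call(rbind, lapply(report$results, `[[`, "violations"))
    if (is.null(v)) v <- .empty_violations()
    utils::write.csv(v, csv, row.names = FALSE)
    out$csv <- csv
  }
  invisible(out)
}

#' Read a run configuration
#'
#' YAML or JSON with keys `env` (preset name or [fh_env()] fields), `profiles`
#' (ids, optionally with threshold overrides), `block_px`.
#'
#' @param path config file.
#' @return list with `env`, `profiles`, `block_px`.
#' @export
fh_read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  env <- if (is.character(cfg$env)) fh_env_preset(cfg$env)
         else do.call(fh_env, cfg$env)
  profiles <- NULL
  if (!is.null(cfg$profiles)) {
    profiles <- lapply(seq_along(cfg$profiles), function(i) {
      p <- cfg$profiles[[i]]
      if (is.character(p)) fh_profile(p)
      else do.call(fh_profile, c(list(id = p$id), p$overrides))
    })
    names(profiles) <- vapply(profiles, `[[`, "", "id")
  }
  list(env = env, profiles = profiles, block_px = cfg$block_px)
}
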