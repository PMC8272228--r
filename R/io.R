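frame_dialects <- c("csv-celsius", "tiff-16bit-scaled")

#' Write a thermal frame to disk
#'
#' Two dialects are supported: `csv-celsius`, a plain comma-separated matrix
#' of degrees C (lossless up to text precision), and `tiff-16bit-scaled`, a
#' 16-bit grayscale TIFF whose integer pixel value `v` encodes
#' `v * scale + offset` degrees C (the default scale 0.01 stores
#' centi-degrees; values are half-even rounded to the nearest code).
#'
#' @param frame A [thermal_frame()].
#' @param path Output file path.
#' @param dialect `"csv-celsius"` or `"tiff-16bit-scaled"`.
#' @param scale,offset Linear code-to-Celsius mapping for the TIFF dialect.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path, dialect = "csv-celsius",
                        scale = 0.01, offset = 0) {
  stopifnot(inherits(frame, "thermal_frame"))
  dialect <- match.arg(dialect, frame_dialects)
  m <- frame$temperatures
  if (dialect == "csv-celsius") {
    data.table::fwrite(data.table::as.data.table(m), path,
                       col.names = FALSE)
  } else {
    v <- round((m - offset) / scale)
    if (any(v < 0) || any(v > 65535))
      stop("temperatures out of representable range for 16-bit TIFF dialect")
    tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  }
  invisible(path)
}

#' Read a thermal frame from disk
#'
#' @inheritParams write_frame
#' @param timestamp_s Timestamp to attach to the frame.
#' @param window Plausibility window in degrees C passed to
#'   [thermal_frame()]; out-of-window values raise a validation error naming
#'   the offending range.
#' @return A [thermal_frame()].
#' @export
read_frame <- function(path, dialect = "csv-celsius", timestamp_s = 0,
                       scale = 0.01, offset = 0, window = c(0, 60)) {
  dialect <- match.arg(dialect, frame_dialects)
  if (!file.exists(path)) stop("cannot read frame: no such file: ", path)
  if (dialect == "csv-celsius") {
    m <- as.matrix(data.table::fread(path, header = FALSE))
    dimnames(m) <- NULL
  } else {
    v <- tiff::readTIFF(path, as.is = TRUE)
    m <- v * scale + offset
  }
  storage.mode(m) <- "double"
  thermal_frame(m, timestamp_s = timestamp_s, window = window)
}

#' Write a session recording as a frame directory plus JSON manifest
#'
#' The manifest (`manifest.json`) lists the per-frame files with their
#' timestamps and embeds the session protocol and identifiers, so a
#' recording round-trips through [read_session()].
#'
#' @param recording A `session_recording` (see [simulate_session()]).
#' @param dir Output directory (created if needed).
#' @param dialect Frame dialect, see [write_frame()].
#' @param scale,offset TIFF code mapping, stored in the manifest.
#' @return Path to the manifest, invisibly.
#' @export
write_session <- function(recording, dir, dialect = "csv-celsius",
                          scale = 0.01, offset = 0) {
  stopifnot(inherits(recording, "session_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (dialect == "csv-celsius") "csv" else "tif"
  files <- sprintf("frame_%04d.%s", seq_along(recording$frames) - 1L, ext)
  for (i in seq_along(recording$frames))
    write_frame(recording$frames[[i]], file.path(dir, files[i]),
                dialect = dialect, scale = scale, offset = offset)
  manifest <- list(
    subject_id = recording$subject_id,
    session_id = recording$session_id,
    dialect = dialect, scale = scale, offset = offset,
    protocol = unclass(recording$protocol),
    frames = data.frame(
      path = files,
      timestamp_s = vapply(recording$frames, `[[`, 0, "timestamp_s")))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read a session recording from a manifest
#'
#' Frames are sorted by timestamp on read; a missing frame file or a
#' duplicated timestamp is a manifest error.
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [write_session()].
#' @return A `session_recording`.
#' @export
read_session <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("cannot read session: no such manifest: ", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  fr <- man$frames
  if (is.null(fr) || nrow(fr) == 0) stop("manifest error: no frames listed")
  if (anyDuplicated(fr$timestamp_s))
    stop("manifest error: duplicate frame timestamps")
  fr <- fr[order(fr$timestamp_s), , drop = FALSE]
  missing <- !file.exists(file.path(dir, fr$path))
  if (any(missing))
    stop("manifest error: missing frame file(s): ",
         paste(fr$path[missing], collapse = ", "))
  p <- man$protocol
  protocol <- session_protocol(p$n_sets, p$reps_per_set, p$rep_rate,
                               p$passive_s, p$recovery_s, p$weight_kg,
                               p$target_muscle, p$arm_side)
  frames <- lapply(seq_len(nrow(fr)), function(i)
    read_frame(file.path(dir, fr$path[i]), dialect = man$dialect,
               timestamp_s = fr$timestamp_s[i],
               scale = man$scale %||% 0.01, offset = man$offset %||% 0))
  session_recording(frames, protocol,
                    subject_id = man$subject_id %||% "unknown",
                    session_id = man$session_id %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a heat map or difference heat map as a colorized PNG
#'
#' Visualization only; PNG exports are never re-ingested by the pipeline.
#' Uses a fixed blue-to-red scale over `zlim` with missing cells black.
#'
#' @param map A `heat_map` or `diff_heat_map`.
#' @param path Output PNG path.
#' @param zlim Color scale limits; defaults to the map's finite range.
#' @param px_per_cell Magnification factor.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(map, path, zlim = NULL, px_per_cell = 4L) {
  m <- unclass_map(map)
  if (is.null(zlim)) zlim <- range(m, na.rm = TRUE)
  if (diff(zlim) <= 0) zlim <- zlim + c(-0.5, 0.5)
  u <- (m - zlim[1]) / (zlim[2] - zlim[1])
  u <- pmin(pmax(u, 0), 1)
  ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  rgbv <- ramp(as.vector(u))
  rgbv[is.na(rgbv)] <- 0
  arr <- array(0, dim = c(nrow(m), ncol(m), 3))
  for (k in 1:3) arr[, , k] <- matrix(rgbv[, k] / 255, nrow(m), ncol(m))
  big <- arr[rep(seq_len(nrow(m)), each = px_per_cell),
             rep(seq_len(ncol(m)), each = px_per_cell), , drop = FALSE]
  png::writePNG(big, path)
  invisible(path)
}

#' Write a heat map as a CSV matrix with a JSON sidecar
#'
#' @param map A `heat_map` or `diff_heat_map`.
#' @param path Output CSV path; the sidecar is written next to it with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
write_heatmap_csv <- function(map, path) {
  m <- unclass_map(map)
  data.table::fwrite(data.table::as.data.table(m), path, col.names = FALSE)
  side <- list(session_id = attr(map, "session_id"))
  if (inherits(map, "diff_heat_map")) side$pair <- attr(map, "pair")
  else side$label <- attr(map, "label")
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE)
  invisible(path)
}

unclass_map <- function(map) {
  m <- map
  attributes(m) <- list(dim = dim(map))
  m
}
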