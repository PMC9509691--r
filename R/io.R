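# Readers and writers for the package's text/image artifacts. Every writer
# emits a provenance header (tool version, seed when known).

.oph_version <- function() as.character(utils::packageVersion("oph"))

#' Write / read a single channel recording
#'
#' Columnar CSV with `#`-prefixed header lines carrying the sampling rate,
#' modulation frequency and channel id, then columns `time_s, volts` at 12+
#' significant digits so a round trip preserves the demodulation result.
#'
#' @param rec a `channel_recording` (see [simulate_acquisition()]).
#' @param path file path.
#' @param seed optional seed recorded in the provenance header.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `channel_recording`.
#' @export
write_recording <- function(rec, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# oph recording v%s", .oph_version()),
               sprintf("# fs=%.12g", rec$fs),
               sprintf("# f_mod=%.12g", rec$f_mod),
               sprintf("# channel_id=%d", rec$channel_id),
               if (!is.null(seed)) sprintf("# seed=%d", seed),
               "time_s,volts"), con)
  t <- (seq_along(rec$samples) - 1) / rec$fs
  writeLines(sprintf("%.12g,%.15g", t, rec$samples), con)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (!length(m)) stop(sprintf("recording header missing field '%s'", key))
    as.numeric(sub(sprintf("^# %s=", key), "", m[1]))
  }
  body <- lines[!grepl("^#", lines)]
  if (!length(body) || body[1] != "time_s,volts")
    stop("malformed recording: expected column header 'time_s,volts'")
  d <- utils::read.csv(text = body)
  structure(list(samples = d$volts, fs = get("fs"), f_mod = get("f_mod"),
                 channel_id = as.integer(get("channel_id"))),
            class = "channel_recording")
}

#' Write / read a four-channel acquisition
#'
#' One recording CSV per channel, named `<prefix>_ch<k>.csv`.
#'
#' @param acq an `oph_acquisition`.
#' @param prefix path prefix for the four files.
#' @param seed optional seed recorded in each header.
#' @return `write_acquisition` returns the four paths invisibly;
#'   `read_acquisition` returns a list of four `channel_recording`s ordered
#'   by channel id.
#' @export
write_acquisition <- function(acq, prefix, seed = NULL) {
  paths <- vapply(seq_along(acq), function(k) {
    p <- sprintf("%s_ch%d.csv", prefix, acq[[k]]$channel_id)
    write_recording(acq[[k]], p, seed = seed)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_acquisition
#' @export
read_acquisition <- function(prefix) {
  recs <- lapply(1:4, function(k) {
    read_recording(sprintf("%s_ch%d.csv", prefix, k))
  })
  structure(recs, class = "oph_acquisition")
}

#' Write / read a calibration as JSON
#'
#' All calibration constants, thresholds, range and fit diagnostic, plus a
#' provenance block (tool version).
#'
#' @param cal an [calibration()] object.
#' @param path file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns an `oph_calibration`.
#' @export
write_calibration <- function(cal, path) {
  obj <- unclass(cal)
  obj$provenance <- list(tool = "oph", version = .oph_version())
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("slope", "intercept", "ph_min", "ph_max", "af_threshold",
              "min_signal"))
    if (is.null(obj[[f]])) stop(sprintf("calibration JSON missing '%s'", f))
  calibration(slope = obj$slope, intercept = obj$intercept,
              ph_min = obj$ph_min, ph_max = obj$ph_max,
              af_threshold = obj$af_threshold, min_signal = obj$min_signal,
              pearson_r = if (is.null(obj$pearson_r)) NA_real_
                          else as.numeric(obj$pearson_r))
}

#' Write / read a cohort as CSV tables
#'
#' Three files in `dir`: `surfaces.csv`, `subjects.csv`, `readings.csv`,
#' with the column layouts produced by [synth_cohort()].
#'
#' @param cohort an `oph_cohort` (or compatible list of data frames).
#' @param dir directory (created if needed).
#' @param seed optional seed recorded in a `provenance.json` alongside.
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns an
#'   `oph_cohort`.
#' @export
write_cohort <- function(cohort, dir, seed = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$surfaces, file.path(dir, "surfaces.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$readings, file.path(dir, "readings.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(tool = "oph", version = .oph_version(),
                            seed = seed),
                       file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  req <- function(file, cols) {
    p <- file.path(dir, file)
    if (!file.exists(p)) stop(sprintf("cohort file missing: %s", file))
    d <- utils::read.csv(p)
    miss <- setdiff(cols, names(d))
    if (length(miss))
      stop(sprintf("%s: missing column(s) %s", file,
                   paste(miss, collapse = ", ")))
    d
  }
  structure(list(
    surfaces = req("surfaces.csv", c("subject_id", "group", "surface_id",
                                     "rank", "rest_ph", "drop_ph")),
    subjects = req("subjects.csv", c("subject_id", "group", "saliva_ph")),
    readings = req("readings.csv", c("subject_id", "group", "surface_id",
                                     "rank", "phase", "replicate", "ph"))),
    class = "oph_cohort")
}

#' Write / read a two-channel frame stack as multi-page TIFF
#'
#' Pages are ordered G then R within each frame, 16-bit unsigned on disk,
#' unit range in memory.
#'
#' @param stack a [frame_stack()]; intensities must lie in `[0, 1]`.
#' @param path TIFF file path.
#' @return `write_frames` returns `path` invisibly; `read_frames` returns a
#'   `frame_stack`.
#' @export
write_frames <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  arr <- unclass(stack)
  if (max(arr) > 1) stop("frame intensities must lie in [0, 1] for 16-bit output")
  pages <- list()
  for (i in seq_len(dim(arr)[4]))
    for (ch in 1:2)
      pages[[length(pages) + 1]] <- arr[, , ch, i]
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% 2 != 0)
    stop("frame TIFF must contain an even number of pages (G,R per frame)")
  nf <- length(pages) / 2
  d <- dim(pages[[1]])
  arr <- array(0, c(d[1], d[2], 2, nf))
  for (i in seq_len(nf)) {
    arr[, , 1, i] <- pages[[2 * i - 1]]
    arr[, , 2, i] <- pages[[2 * i]]
  }
  frame_stack(arr)
}

#' Export a pH image
#'
#' Writes the pH map as a 32-bit TIFF scaled by 1/14 (the 0-14 pH scale maps
#' onto the unit range the TIFF stores; multiply by 14 to recover pH),
#' with invalid pixels as 0, and optionally renders a PNG heatmap with a
#' colour bar.
#'
#' @param img a `ph_image` (see [ph_map()]).
#' @param path TIFF path.
#' @param png_path optional PNG heatmap path.
#' @param zlim pH display limits for the heatmap.
#' @return `path`, invisibly.
#' @export
write_ph_image <- function(img, path, png_path = NULL, zlim = NULL) {
  stopifnot(inherits(img, "ph_image"))
  m <- img$ph / 14
  m[!img$valid | is.na(m)] <- 0
  tiff::writeTIFF(m, path, bits.per.sample = 32, reduce = FALSE)
  if (!is.null(png_path)) render_heatmap(img, png_path, zlim = zlim)
  invisible(path)
}

#' Render a pH heatmap PNG with a colour bar
#'
#' @inheritParams write_ph_image
#' @param png_path PNG output path.
#' @return `png_path`, invisibly.
#' @export
render_heatmap <- function(img, png_path, zlim = NULL) {
  vals <- img$ph[img$valid]
  if (is.null(zlim))
    zlim <- if (length(vals)) range(vals) else c(4, 7.5)
  if (diff(zlim) == 0) zlim <- zlim + c(-0.5, 0.5)
  z <- img$ph
  z[!img$valid] <- NA
  pal <- grDevices::hcl.colors(64, "Spectral")
  grDevices::png(png_path, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(1:2, 1), widths = c(5, 1))
  graphics::par(mar = c(2, 2, 2, 1))
  graphics::image(t(z[nrow(z):1, , drop = FALSE]), col = pal, zlim = zlim,
                  axes = FALSE, main = "pH")
  graphics::par(mar = c(2, 1, 2, 3))
  ramp <- seq(zlim[1], zlim[2], length.out = 64)
  graphics::image(1, ramp, matrix(ramp, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(4)
  invisible(png_path)
}
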