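# Per-pixel pH mapping for two-channel (G ~ 520 nm, R ~ 549 nm) frame
# stacks: frame averaging, ratio-to-pH conversion with validity masking,
# rest/drop difference maps, and a synthetic tooth-phantom generator.

#' Two-channel frame stack
#'
#' @param frames either a 4-D array `[rows, cols, channel, frame]` with
#'   channel 1 = G (520 nm band) and channel 2 = R (549 nm band), or a list
#'   of 3-D arrays `[rows, cols, channel]`, one per frame. Intensities must
#'   be nonnegative; in-memory convention is unit range (16-bit unsigned on
#'   disk, see [write_frames()]).
#' @return An object of class `frame_stack` (the 4-D array with attributes).
#' @export
frame_stack <- function(frames) {
  if (is.list(frames)) {
    stopifnot(length(frames) >= 1)
    dims <- dim(frames[[1]])
    stopifnot(length(dims) == 3, dims[3] == 2)
    arr <- array(unlist(frames), dim = c(dims, length(frames)))
  } else {
    arr <- frames
  }
  stopifnot(length(dim(arr)) == 4, dim(arr)[3] == 2, all(arr >= 0),
            all(is.finite(arr)))
  structure(arr, class = "frame_stack", channels = c("G", "R"))
}

#' Number of frames in a stack
#' @param stack a [frame_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack)[4]

#' Average the first n frames of a stack
#'
#' Per-pixel, per-channel arithmetic mean, used to suppress frame noise
#' (averaging 10 frames reduces white noise SD by about `1/sqrt(10)`).
#'
#' @param stack a [frame_stack()].
#' @param n number of leading frames to average (default: all).
#' @return A 3-D array `[rows, cols, channel]`.
#' @export
average_frames <- function(stack, n = n_frames(stack)) {
  stopifnot(inherits(stack, "frame_stack"), n >= 1)
  if (n > n_frames(stack))
    stop("n exceeds the number of frames in the stack")
  d <- dim(stack)
  arr <- unclass(stack)
  out <- array(0, d[1:3])
  for (i in seq_len(n)) out <- out + arr[, , , i]
  out / n
}

#' Per-pixel pH map from a two-channel image
#'
#' Computes the per-pixel ratio `(G - R) / (G + R)` and applies the linear
#' calibration. A pixel is invalid when its total signal `G + R` falls below
#' `min_signal` (air bubbles, background) or its predicted pH falls outside
#' the calibration range. The arithmetic is identical to the scalar path
#' `predict_ph(compute_ratio(G, R), cal)`.
#'
#' @param image a 3-D array `[rows, cols, 2]` (G then R), e.g. from
#'   [average_frames()].
#' @param cal an [calibration()] object; the default falls back to the
#'   point-device constants.
#' @param min_signal minimum `G + R` for a valid pixel; default 2% of the
#'   image's 99th-percentile total signal.
#' @return An object of class `ph_image`: list with matrices `ph` (pH,
#'   `NA` where the total signal is zero) and `valid`, plus `summary`
#'   (mean/median over valid pixels and the valid count).
#' @export
ph_map <- function(image, cal = calibration(), min_signal = NULL) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 2)
  g <- image[, , 1]; r <- image[, , 2]
  stopifnot(all(g >= 0), all(r >= 0))
  total <- g + r
  if (is.null(min_signal))
    min_signal <- 0.02 * stats::quantile(total, 0.99, names = FALSE)
  ratio <- matrix(NA_real_, nrow(total), ncol(total))
  nz <- total > 0
  ratio[nz] <- (g[nz] - r[nz]) / total[nz]
  ph <- cal$slope * ratio + cal$intercept
  valid <- nz & total >= min_signal &
    !is.na(ph) & ph >= cal$ph_min & ph <= cal$ph_max
  .ph_image(ph, valid)
}

.ph_image <- function(ph, valid) {
  vals <- ph[valid]
  summary <- if (length(vals))
    list(mean = mean(vals), median = stats::median(vals),
         n_valid = length(vals))
  else list(mean = NA_real_, median = NA_real_, n_valid = 0L)
  structure(list(ph = ph, valid = valid, summary = summary),
            class = "ph_image")
}

#' @export
print.ph_image <- function(x, ...) {
  cat(sprintf("pH image %d x %d: %d valid pixels", nrow(x$ph), ncol(x$ph),
              x$summary$n_valid))
  if (x$summary$n_valid > 0)
    cat(sprintf(", mean pH %.3f, median %.3f", x$summary$mean,
                x$summary$median))
  cat("\n")
  invisible(x)
}

#' Rest-minus-drop pH difference map
#'
#' Per-pixel `rest - drop` where both maps are valid; the validity mask is
#' the intersection and the summary is computed over it. An empty joint
#' mask raises a warning and an undefined summary.
#'
#' @param rest,drop `ph_image` objects of identical dimensions.
#' @return A `ph_image` holding the difference (its `ph` field is a pH
#'   difference, not an absolute pH).
#' @export
diff_map <- function(rest, drop) {
  stopifnot(inherits(rest, "ph_image"), inherits(drop, "ph_image"))
  if (!all(dim(rest$ph) == dim(drop$ph)))
    stop("rest and drop maps have different dimensions")
  valid <- rest$valid & drop$valid
  d <- matrix(NA_real_, nrow(rest$ph), ncol(rest$ph))
  d[valid] <- rest$ph[valid] - drop$ph[valid]
  if (!any(valid))
    warning("disjoint validity masks: difference map has no valid pixels",
            call. = FALSE)
  .ph_image(d, valid)
}

#' Render a synthetic two-channel frame stack from a pH field
#'
#' Tooth-phantom generator: for each pixel the expected G and R intensities
#' are computed from the photophysics model at the pixel's ground-truth pH
#' (G = dianion-band channel, R = anion-band channel), scaled to unit range,
#' optionally stamped with zero-signal circular "air bubbles", replicated
#' over frames and degraded with additive Gaussian noise.
#'
#' @param ph_field numeric matrix of ground-truth pH per pixel.
#' @param model a [fluorescein_model()].
#' @param n_frames number of frames to render (default 10).
#' @param noise_sd per-frame additive Gaussian noise SD, in units of the
#'   unit-scaled intensities.
#' @param bubbles optional list of `c(row, col, radius)` circles set to zero
#'   signal in both channels.
#' @param seed optional integer seed.
#' @param config an [instrument_config()]; its first two filter passbands
#'   define the G and R bands.
#' @return A [frame_stack()] with attributes `ph_field` and `bubble_mask`.
#' @export
synth_frames <- function(ph_field, model = fluorescein_model(),
                         n_frames = 10, noise_sd = 0, bubbles = NULL,
                         seed = NULL, config = instrument_config()) {
  stopifnot(is.matrix(ph_field), all(is.finite(ph_field)), n_frames >= 1,
            noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  gr <- .gr_signals(as.vector(ph_field), model, config)
  g <- gr$g; r <- gr$r
  scale <- max(g + r)
  g <- matrix(g / scale, nrow(ph_field)); r <- matrix(r / scale, nrow(ph_field))
  bubble_mask <- matrix(FALSE, nrow(ph_field), ncol(ph_field))
  if (!is.null(bubbles)) {
    rows <- row(bubble_mask); cols <- col(bubble_mask)
    for (b in bubbles)
      bubble_mask <- bubble_mask |
        ((rows - b[1])^2 + (cols - b[2])^2 <= b[3]^2)
    g[bubble_mask] <- 0; r[bubble_mask] <- 0
  }
  d <- c(dim(ph_field), 2, n_frames)
  arr <- array(0, d)
  for (i in seq_len(n_frames)) {
    gi <- g; ri <- r
    if (noise_sd > 0) {
      gi <- pmax(gi + stats::rnorm(length(gi), 0, noise_sd), 0)
      ri <- pmax(ri + stats::rnorm(length(ri), 0, noise_sd), 0)
    }
    arr[, , 1, i] <- gi; arr[, , 2, i] <- ri
  }
  out <- frame_stack(arr)
  attr(out, "ph_field") <- ph_field
  attr(out, "bubble_mask") <- bubble_mask
  out
}

#' Fit an imaging calibration from the forward model
#'
#' Builds the image-device analogue of the buffer calibration: renders the
#' model's noiseless G/R ratio at a set of pH levels and fits the linear
#' ratio-to-pH map through them, the way a separate imaging calibration
#' curve is built for an imaging instrument.
#'
#' @param levels pH levels of the synthetic calibration buffers.
#' @param model a [fluorescein_model()].
#' @param config an [instrument_config()] providing the G and R passbands.
#' @param ph_range accepted range stored in the calibration.
#' @return An `oph_calibration`.
#' @export
imaging_calibration <- function(levels = c(4.5, 5.5, 6.5, 7.5),
                                model = fluorescein_model(),
                                config = instrument_config(),
                                ph_range = c(4, 7.5)) {
  stopifnot(length(levels) >= 2)
  gr <- .gr_signals(levels, model, config)
  ratios <- compute_ratio(gr$g, gr$r)
  fit_calibration(ratios, levels, ph_min = ph_range[1], ph_max = ph_range[2])
}

# noiseless dye-only G/R expected intensities at pH values; the per-pixel
# signal is affine in the dianion fraction, so only four in-band integrals
# are needed regardless of the number of pixels
.gr_signals <- function(ph, model, config) {
  wl <- .oph_default_wavelengths()
  band <- function(profile, k) {
    expected_channel_signal(wl, profile, config$filter_centers_nm[k],
                            config$filter_fwhm_nm[k])
  }
  dia <- .gaussian_profile(wl, model$dianion_peak_nm, model$dianion_fwhm_nm,
                           model$dianion_brightness)
  ani <- .gaussian_profile(wl, model$anion_peak_nm, model$anion_fwhm_nm,
                           model$anion_brightness)
  fd <- species_fractions(ph, model$pka)$f_dianion
  list(g = fd * band(dia, 1) + (1 - fd) * band(ani, 1),
       r = fd * band(dia, 2) + (1 - fd) * band(ani, 2))
}
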