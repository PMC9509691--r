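# Ratio computation, linear pH calibration, quality gating, replicate
# aggregation and pooled-SD repeatability.

#' Linear pH calibration
#'
#' The point-device calibration maps the normalised two-channel ratio to pH
#' as `pH = slope * ratio + intercept`. The defaults are the device's
#' published constants (slope 10.34, intercept 3.42) with the accepted pH
#' range 4-7.5. Quality thresholds default to fractions of the instrument
#' full scale: autofluorescence above 5% of full scale, or total fluorescein
#' signal below 1%, rejects a reading.
#'
#' @param slope pH per unit ratio; nonzero.
#' @param intercept pH at zero ratio.
#' @param ph_min,ph_max accepted pH range.
#' @param af_threshold maximum acceptable autofluorescence amplitude
#'   (channel-signal units, as returned by [demodulate()]).
#' @param min_signal minimum acceptable `f520 + f550` amplitude.
#' @param pearson_r fit diagnostic (correlation of the calibration pairs),
#'   `NA` for a calibration not obtained from [fit_calibration()].
#' @return An object of class `oph_calibration`.
#' @examples
#' cal <- calibration()
#' predict_ph(0, cal)    # the intercept, 3.42
#' predict_ph(0.2, cal)  # 5.488
#' @export
calibration <- function(slope = 10.34, intercept = 3.42,
                        ph_min = 4, ph_max = 7.5,
                        af_threshold = 0.05 * full_scale_signal(),
                        min_signal = 0.01 * full_scale_signal(),
                        pearson_r = NA_real_) {
  stopifnot(is.finite(slope), slope != 0, is.finite(intercept),
            ph_min < ph_max, af_threshold > 0, min_signal >= 0)
  structure(list(slope = slope, intercept = intercept,
                 ph_min = ph_min, ph_max = ph_max,
                 af_threshold = af_threshold, min_signal = min_signal,
                 pearson_r = pearson_r),
            class = "oph_calibration")
}

#' @export
print.oph_calibration <- function(x, ...) {
  cat(sprintf("oph calibration: pH = %.4g * ratio + %.4g\n", x$slope,
              x$intercept))
  cat(sprintf("  accepted range [%.2f, %.2f], AF threshold %.3g, min signal %.3g",
              x$ph_min, x$ph_max, x$af_threshold, x$min_signal))
  if (is.finite(x$pearson_r)) cat(sprintf(", r = %.4f", x$pearson_r))
  cat("\n")
  invisible(x)
}

#' Normalised two-channel ratio
#'
#' `(ch1 - ch2) / (ch1 + ch2)`: the dye-amount- and distance-independent
#' quantity the calibration maps to pH.
#'
#' @param ch1,ch2 nonnegative channel amplitudes (vectors allowed).
#' @return Ratio in `[-1, 1]`; antisymmetric under swapping the channels.
#' @export
compute_ratio <- function(ch1, ch2) {
  stopifnot(length(ch1) == length(ch2), all(ch1 >= 0), all(ch2 >= 0))
  if (any(ch1 + ch2 == 0))
    stop("undefined ratio: ch1 + ch2 is zero")
  (ch1 - ch2) / (ch1 + ch2)
}

#' Predict pH from a ratio
#'
#' Applies the linear calibration `pH = slope * ratio + intercept`. Range
#' enforcement is the job of [qc_evaluate()], not of this function.
#'
#' @param ratio normalised channel ratio in `[-1, 1]` (vector allowed).
#' @param cal an [calibration()] object.
#' @return Predicted pH.
#' @export
predict_ph <- function(ratio, cal = calibration()) {
  stopifnot(inherits(cal, "oph_calibration"), is.numeric(ratio),
            all(is.finite(ratio)))
  if (any(abs(ratio) > 1 + 1e-12))
    stop("ratio must lie in [-1, 1]")
  cal$slope * ratio + cal$intercept
}

#' Fit a linear calibration from (ratio, reference pH) pairs
#'
#' Ordinary least squares of reference pH on ratio (the direction in which
#' the calibration is applied), mirroring the buffer protocol in which each
#' of a handful of buffered fluorescein solutions is measured repeatedly.
#' The Pearson correlation of the pairs is stored as the fit diagnostic,
#' computed on the pairs exactly as supplied.
#'
#' @param ratio normalised channel ratios.
#' @param ref_ph reference pH of each measurement (e.g. from a lab pH meter).
#' @param ph_min,ph_max,af_threshold,min_signal carried into the returned
#'   calibration; defaults as in [calibration()].
#' @return An `oph_calibration` with fitted `slope`, `intercept` and
#'   `pearson_r`.
#' @examples
#' r <- c(0.1, 0.2, 0.3, 0.4)
#' fit_calibration(r, 10.34 * r + 3.42)  # exact line recovery
#' @export
fit_calibration <- function(ratio, ref_ph,
                            ph_min = 4, ph_max = 7.5,
                            af_threshold = 0.05 * full_scale_signal(),
                            min_signal = 0.01 * full_scale_signal()) {
  stopifnot(length(ratio) == length(ref_ph), length(ratio) >= 2,
            all(is.finite(ratio)), all(is.finite(ref_ph)))
  if (length(unique(ratio)) < 2)
    stop("degenerate calibration: all ratio values are equal")
  fit <- stats::lm(ref_ph ~ ratio)
  co <- stats::coef(fit)
  calibration(slope = unname(co[2]), intercept = unname(co[1]),
              ph_min = ph_min, ph_max = ph_max,
              af_threshold = af_threshold, min_signal = min_signal,
              pearson_r = stats::cor(ratio, ref_ph))
}

#' Quality-gate a set of channel amplitudes into a pH reading
#'
#' Applies the rejection rules in fixed order of precedence and reports the
#' first failure: high autofluorescence (`af475 > af_threshold`), then low
#' fluorescein signal (`f520 + f550 < min_signal`), then predicted pH
#' outside the accepted range. Accepted readings carry a pH inside
#' `[ph_min, ph_max]`.
#'
#' @param amplitudes a [channel_amplitudes()] object.
#' @param cal an [calibration()] object.
#' @return An object of class `oph_reading`: list with `amplitudes`,
#'   `ratio`, `ph`, `status` (`"accepted"` or `"rejected"`) and
#'   `reject_reason` (`"none"`, `"high_af"`, `"low_signal"`,
#'   `"out_of_range"`).
#' @export
qc_evaluate <- function(amplitudes, cal = calibration()) {
  stopifnot(inherits(amplitudes, "channel_amplitudes"),
            inherits(cal, "oph_calibration"))
  reading <- function(ratio, ph, status, reason) {
    structure(list(amplitudes = amplitudes, ratio = ratio, ph = ph,
                   status = status, reject_reason = reason),
              class = "oph_reading")
  }
  if (amplitudes$af475 > cal$af_threshold)
    return(reading(NA_real_, NA_real_, "rejected", "high_af"))
  total <- amplitudes$f520 + amplitudes$f550
  if (total < cal$min_signal || total == 0)
    return(reading(NA_real_, NA_real_, "rejected", "low_signal"))
  ratio <- compute_ratio(amplitudes$f520, amplitudes$f550)
  ph <- predict_ph(ratio, cal)
  if (ph < cal$ph_min || ph > cal$ph_max)
    return(reading(ratio, ph, "rejected", "out_of_range"))
  reading(ratio, ph, "accepted", "none")
}

#' @export
print.oph_reading <- function(x, ...) {
  if (x$status == "accepted")
    cat(sprintf("oph reading: pH %.3f (ratio %.4f), accepted\n", x$ph,
                x$ratio))
  else
    cat(sprintf("oph reading: rejected (%s)\n", x$reject_reason))
  invisible(x)
}

#' Aggregate replicate pH readings at one spot
#'
#' Each tooth surface is measured up to three times; the mean of the
#' accepted replicates is the surface's value. Spots that lost replicates to
#' quality gating are retained with reduced n.
#'
#' @param phs accepted pH values (length >= 1).
#' @return List with `mean`, `sd` (sample SD, `NA` when n < 2) and `n`.
#' @export
aggregate_replicates <- function(phs) {
  phs <- phs[is.finite(phs)]
  if (length(phs) == 0) stop("no accepted replicate readings to aggregate")
  list(mean = mean(phs),
       sd = if (length(phs) >= 2) stats::sd(phs) else NA_real_,
       n = length(phs))
}

#' Pooled standard deviation across replicate groups
#'
#' `sqrt( sum_i (n_i - 1) s_i^2 / sum_i (n_i - 1) )` over the replicate
#' triplets: the device's repeatability metric, the average spread of
#' readings about their triplet mean. Groups with fewer than two readings
#' carry no spread information and are excluded.
#'
#' @param groups list of numeric vectors, one per replicate group.
#' @return Pooled SD (same units as the readings).
#' @export
pooled_sd <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1)
  ns <- lengths(groups)
  keep <- ns >= 2
  if (!any(keep)) stop("pooled SD needs at least one group with n >= 2")
  vars <- vapply(groups[keep], stats::var, numeric(1))
  dfs <- ns[keep] - 1
  sqrt(sum(dfs * vars) / sum(dfs))
}
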