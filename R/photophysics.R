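# Forward model: pH-dependent fluorescein emission through the instrument's
# four filtered photodiode channels, pulsed excitation and additive noise.

# internal wavelength grid (nm) used wherever a default grid is needed
.oph_default_wavelengths <- function() seq(400, 700, by = 0.25)

# fixed background emission widths (nm FWHM); the model type carries only the
# background brightnesses, so the widths are package constants: enamel/tissue
# autofluorescence is broad, porphyrin emission is a narrow red band.
.AF_PEAK_NM <- 475
.AF_FWHM_NM <- 100
.PPIX_PEAK_NM <- 632
.PPIX_FWHM_NM <- 20

#' Fluorescein photophysics model
#'
#' Parameters of the two fluorescent protonation states of sodium fluorescein
#' (anion and dianion) plus background emitters. Species emission profiles are
#' Gaussian in wavelength; excitation efficiency at the 420 nm band is folded
#' into the per-species brightness.
#'
#' @param pka acid-base constant of the anion/dianion equilibrium. The default
#'   6.43 is the literature value for fluorescein in aqueous solution.
#' @param dianion_peak_nm,dianion_fwhm_nm,dianion_brightness emission peak
#'   centre (nm), full width at half maximum (nm) and relative brightness of
#'   the dianion (the high-pH species, peaking near 520 nm).
#' @param anion_peak_nm,anion_fwhm_nm,anion_brightness same for the anion
#'   (the low-pH species, peaking near 550 nm). The default brightness 0.30
#'   reflects the anion's much lower quantum yield and is chosen so the
#'   simulated ratio-vs-pH curve is near-linear on pH 4-7.5.
#' @param af_brightness relative brightness of broad tissue/enamel
#'   autofluorescence centred near 475 nm.
#' @param ppix_brightness relative brightness of bacterial porphyrin emission
#'   centred near 632 nm.
#' @return An object of class `fluorescein_model`.
#' @examples
#' m <- fluorescein_model()
#' species_fractions(7.0, m$pka)
#' @export
fluorescein_model <- function(pka = 6.43,
                              dianion_peak_nm = 520, dianion_fwhm_nm = 35,
                              dianion_brightness = 1.0,
                              anion_peak_nm = 550, anion_fwhm_nm = 45,
                              anion_brightness = 0.30,
                              af_brightness = 0.05,
                              ppix_brightness = 0.02) {
  stopifnot(is.finite(pka),
            dianion_fwhm_nm > 0, anion_fwhm_nm > 0,
            dianion_brightness >= 0, anion_brightness >= 0,
            af_brightness >= 0, ppix_brightness >= 0)
  if (!(dianion_peak_nm < anion_peak_nm))
    stop("dianion_peak_nm must be below anion_peak_nm")
  structure(list(pka = pka,
                 dianion_peak_nm = dianion_peak_nm,
                 dianion_fwhm_nm = dianion_fwhm_nm,
                 dianion_brightness = dianion_brightness,
                 anion_peak_nm = anion_peak_nm,
                 anion_fwhm_nm = anion_fwhm_nm,
                 anion_brightness = anion_brightness,
                 af_brightness = af_brightness,
                 ppix_brightness = ppix_brightness),
            class = "fluorescein_model")
}

#' Instrument configuration
#'
#' Electronics and optics of the point-probe device: a blue LED pulsed at
#' `f_mod`, four photodiode channels behind ideal rectangular band-pass
#' filters, a transimpedance stage and a voltage stage, sampled at `fs`.
#'
#' @param f_mod LED modulation frequency, Hz (device default 500).
#' @param fs sampling rate, Hz (device default 10000).
#' @param duration_s acquisition window, s; `duration_s * f_mod` must be a
#'   whole number of modulation cycles.
#' @param filter_centers_nm,filter_fwhm_nm centre and FWHM (nm) of the four
#'   channel filters: fluorescein dianion (524/24), fluorescein anion
#'   (549/12), autofluorescence (475/20), porphyrin (632/22).
#' @param gain_v_per_a transimpedance gain, V/A (default 1e7).
#' @param gain_stage2 second-stage voltage gain, V/V (default 11).
#' @param responsivity_a photocurrent per unit integrated spectral signal,
#'   A; sets the absolute scale of the simulated voltages.
#' @param noise_sd_v additive white Gaussian noise SD on the sampled voltage, V.
#' @param ambient_dc_v constant ambient-light voltage offset, V.
#' @param ambient_flicker amplitude (V) of a 120 Hz ambient flicker term.
#' @param adc_fullscale_v data-acquisition full-scale voltage, V; used to
#'   express quality-control thresholds as fractions of full scale.
#' @return An object of class `instrument_config`.
#' @export
instrument_config <- function(f_mod = 500, fs = 10000, duration_s = 1,
                              filter_centers_nm = c(524, 549, 475, 632),
                              filter_fwhm_nm = c(24, 12, 20, 22),
                              gain_v_per_a = 1e7, gain_stage2 = 11,
                              responsivity_a = 1e-9,
                              noise_sd_v = 0.005,
                              ambient_dc_v = 0.1,
                              ambient_flicker = 0.05,
                              adc_fullscale_v = 10) {
  stopifnot(f_mod > 0, fs > 0, duration_s > 0,
            length(filter_centers_nm) == 4, length(filter_fwhm_nm) == 4,
            all(filter_fwhm_nm > 0),
            gain_v_per_a > 0, gain_stage2 > 0, responsivity_a > 0,
            noise_sd_v >= 0, adc_fullscale_v > 0)
  if (f_mod >= fs / 2)
    stop("f_mod must be below the Nyquist frequency fs/2")
  n_cycles <- duration_s * f_mod
  if (abs(n_cycles - round(n_cycles)) > 1e-9)
    stop("duration_s * f_mod must be an integer (whole modulation cycles)")
  structure(list(f_mod = f_mod, fs = fs, duration_s = duration_s,
                 filter_centers_nm = filter_centers_nm,
                 filter_fwhm_nm = filter_fwhm_nm,
                 gain_v_per_a = gain_v_per_a, gain_stage2 = gain_stage2,
                 responsivity_a = responsivity_a,
                 noise_sd_v = noise_sd_v,
                 ambient_dc_v = ambient_dc_v,
                 ambient_flicker = ambient_flicker,
                 adc_fullscale_v = adc_fullscale_v),
            class = "instrument_config")
}

#' Anion/dianion fractions at a given pH
#'
#' Two-state logistic partition of fluorescein between its fluorescent
#' protonation states: `f_dianion = 1 / (1 + 10^(pka - ph))`.
#'
#' @param ph pH value(s); finite.
#' @param pka acid-base constant.
#' @return A list with numeric components `f_anion` and `f_dianion`, each the
#'   length of `ph`; the two sum to 1 elementwise.
#' @examples
#' species_fractions(6.43)          # (0.5, 0.5) at the midpoint
#' species_fractions(9)$f_dianion   # ~0.997: almost all dianion
#' @export
species_fractions <- function(ph, pka = 6.43) {
  stopifnot(is.numeric(ph), all(is.finite(ph)), is.finite(pka))
  f_d <- 1 / (1 + 10^(pka - ph))
  list(f_anion = 1 - f_d, f_dianion = f_d)
}

.gaussian_profile <- function(wl, peak, fwhm, brightness) {
  brightness * exp(-4 * log(2) * (wl - peak)^2 / fwhm^2)
}

#' Fluorescein emission spectrum at a given pH
#'
#' Mixture of the anion and dianion Gaussian emission profiles weighted by
#' their pH-dependent fractions. Background emitters (autofluorescence,
#' porphyrin) are not part of the dye spectrum; they enter the channel model
#' through [channel_signals()].
#'
#' @param ph a single pH value.
#' @param wavelengths ascending wavelength grid, nm.
#' @param model a [fluorescein_model()].
#' @return Nonnegative intensity at each wavelength.
#' @export
emission_spectrum <- function(ph, wavelengths = .oph_default_wavelengths(),
                              model = fluorescein_model()) {
  stopifnot(length(ph) == 1, is.finite(ph), length(wavelengths) > 0)
  if (is.unsorted(wavelengths)) stop("wavelengths must be sorted ascending")
  fr <- species_fractions(ph, model$pka)
  fr$f_dianion * .gaussian_profile(wavelengths, model$dianion_peak_nm,
                                   model$dianion_fwhm_nm,
                                   model$dianion_brightness) +
    fr$f_anion * .gaussian_profile(wavelengths, model$anion_peak_nm,
                                   model$anion_fwhm_nm,
                                   model$anion_brightness)
}

#' Integrate a spectrum over an ideal rectangular passband
#'
#' @param wavelengths ascending wavelength grid, nm.
#' @param spectrum intensity at each wavelength.
#' @param filter_center_nm,filter_fwhm_nm passband centre and width, nm;
#'   transmission is 1 inside `centre +/- fwhm/2` and 0 outside.
#' @return Integrated intensity (trapezoidal rule over the in-band grid).
#' @export
expected_channel_signal <- function(wavelengths, spectrum,
                                    filter_center_nm, filter_fwhm_nm) {
  stopifnot(length(wavelengths) == length(spectrum), filter_fwhm_nm > 0)
  lo <- filter_center_nm - filter_fwhm_nm / 2
  hi <- filter_center_nm + filter_fwhm_nm / 2
  inside <- wavelengths >= lo & wavelengths <= hi
  if (sum(inside) < 2)
    stop("filter passband lies outside the wavelength grid")
  wl <- wavelengths[inside]
  sp <- spectrum[inside]
  sum(diff(wl) * (sp[-1] + sp[-length(sp)]) / 2)
}

#' Expected per-channel signals for a ground-truth pH
#'
#' Integrates the fluorescein emission spectrum plus the background emitters
#' (broad autofluorescence near 475 nm, porphyrin near 632 nm) over each of
#' the four channel passbands. These are the quantities the lock-in chain
#' recovers, up to the square-wave demodulation gain.
#'
#' @inheritParams emission_spectrum
#' @param config an [instrument_config()].
#' @return Named numeric vector `c(f520, f550, af475, p632)` in integrated
#'   spectral units.
#' @export
channel_signals <- function(ph, model = fluorescein_model(),
                            config = instrument_config()) {
  wl <- .oph_default_wavelengths()
  spec <- emission_spectrum(ph, wl, model) +
    .gaussian_profile(wl, .AF_PEAK_NM, .AF_FWHM_NM, model$af_brightness) +
    .gaussian_profile(wl, .PPIX_PEAK_NM, .PPIX_FWHM_NM, model$ppix_brightness)
  s <- vapply(1:4, function(k) {
    expected_channel_signal(wl, spec, config$filter_centers_nm[k],
                            config$filter_fwhm_nm[k])
  }, numeric(1))
  names(s) <- c("f520", "f550", "af475", "p632")
  s
}

#' Instrument full-scale amplitude in channel-signal units
#'
#' The data-acquisition full-scale voltage referred back through the two gain
#' stages and the responsivity. Quality-control thresholds default to
#' fractions of this value.
#'
#' @param config an [instrument_config()].
#' @return Full-scale amplitude in the same units as [channel_signals()].
#' @export
full_scale_signal <- function(config = instrument_config()) {
  config$adc_fullscale_v /
    (config$gain_v_per_a * config$gain_stage2 * config$responsivity_a)
}

#' Simulate a four-channel acquisition
#'
#' Renders the pulsed-LED photodetector voltages for a ground-truth pH:
#' `v(t) = G1 * G2 * responsivity * S_k * m(t) + ambient + noise`, where
#' `S_k` is the channel's expected signal, `m(t)` a 50%-duty square wave at
#' the modulation frequency, ambient a DC offset plus 120 Hz flicker, and
#' noise additive white Gaussian.
#'
#' @inheritParams channel_signals
#' @param seed optional integer seed; identical seeds give identical samples.
#' @return An object of class `oph_acquisition`: a list of four
#'   `channel_recording` objects (fields `samples`, `fs`, `f_mod`,
#'   `channel_id`), with the configuration attached as an attribute.
#' @examples
#' acq <- simulate_acquisition(6.5, seed = 1)
#' demodulate(acq)
#' @export
simulate_acquisition <- function(ph, model = fluorescein_model(),
                                 config = instrument_config(), seed = NULL) {
  stopifnot(inherits(model, "fluorescein_model"),
            inherits(config, "instrument_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- round(config$fs * config$duration_s)
  t <- (seq_len(n) - 1) / config$fs
  m <- as.numeric((t * config$f_mod) %% 1 < 0.5)
  gain <- config$gain_v_per_a * config$gain_stage2 * config$responsivity_a
  s <- channel_signals(ph, model, config)
  ambient <- config$ambient_dc_v +
    config$ambient_flicker * sin(2 * pi * 120 * t)
  recs <- lapply(1:4, function(k) {
    v <- gain * s[k] * m + ambient
    if (config$noise_sd_v > 0)
      v <- v + stats::rnorm(n, sd = config$noise_sd_v)
    structure(list(samples = v, fs = config$fs, f_mod = config$f_mod,
                   channel_id = k),
              class = "channel_recording")
  })
  structure(recs, class = "oph_acquisition", config = config, ph = ph)
}
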