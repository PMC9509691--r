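---
title: "Methods: simulation, calibration and analysis of ratiometric optical pH sensing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, calibration and analysis of ratiometric optical pH sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oph)
```

## The measurement model

Sodium fluorescein in aqueous solution is an equilibrium mixture of four
protonation states of which only two fluoresce: the anion, dominant in acid
conditions, and the dianion, dominant above neutrality. `oph` models the
fluorescent pair as a two-state logistic partition,

$$f_\mathrm{dianion}(\mathrm{pH}) = \frac{1}{1 + 10^{\,pK_a - \mathrm{pH}}},
\qquad f_\mathrm{anion} = 1 - f_\mathrm{dianion},$$

with $pK_a = 6.43$ by default (the literature value for the fluorescein
anion/dianion equilibrium; it is an explicit model parameter). The emitted
spectrum is the fraction-weighted mixture of two Gaussian profiles. The
non-fluorescent cation and neutral species are deliberately out of model:
on the 4–7.5 working range their populations change little, but their
absence is one reason the simulated ratio curve is *more* sigmoidal than a
real cuvette measurement (see "Calibration buffers" below).

The instrument model follows the device architecture: an LED pulsed as a
50%-duty square wave at `f_mod` = 500 Hz, four photodiode channels behind
ideal rectangular band-pass filters (524/24, 549/12, 475/20, 632/22 nm —
dianion, anion, autofluorescence, porphyrin), a transimpedance gain of
1e7 V/A, a voltage gain of 11 V/V, sampling at 10 kHz. The acquisition is

$$v_k(t) = G_1 G_2\, \rho\, S_k\, m(t) + v_\mathrm{DC}
 + A_{120}\sin(2\pi\,120\,t) + \varepsilon(t),$$

where $S_k$ is the channel's in-band spectral integral, $\rho$ the
responsivity (1e-9 A per signal unit by default), $m(t)$ the square wave
and $\varepsilon$ additive white Gaussian noise (default SD 5 mV, a quiet
photodiode front end). Shot-noise scaling and optical-fibre geometry are
not modelled. The 120 Hz flicker and DC terms exist purely to exercise the
background rejection of the demodulator.

## Lock-in demodulation

`lockin_amplitude()` truncates the record to a whole number of modulation
cycles, FFTs a rectangular window, and reports $2|X_k|/N$ at the bin
nearest `f_mod` (ties toward the lower frequency). Over whole cycles, DC
and any interferer completing an integer number of cycles are exactly
orthogonal to the modulation bin, which is what makes the method robust to
clinical lighting. No taper is applied and no phase is estimated; both are
unnecessary when the window is cycle-aligned and only the magnitude is
used.

One numerical subtlety is the demodulation gain of the sampled square
wave. A continuous 50%-duty unit square wave has fundamental amplitude
$2/\pi \approx 0.6366$; the *sampled* square at the device's 20 samples
per cycle has fundamental $2/(20 \sin(\pi/20)) \approx 0.6392$, about 0.4%
higher. The package adopts the exact discrete value as its amplitude
convention (`lockin_square_gain()`); the forward model and the demodulator
agree with each other to machine precision, and with the continuous-time
coefficient to 1%. Acquisition windows default to 1 s per reading (a
compromise matching the few-seconds-per-spot clinical cadence; it is
configurable).

Demodulated amplitudes are divided by the gain chain
($G_1 G_2 \rho$), so they are in channel-signal units and comparable
across instrument configurations; the two-channel ratio is unaffected by
any common scale.

## Calibration, thresholds, quality gating

`predict_ph()` applies the linear map $\mathrm{pH} = a\,r + b$ with the
device constants $a = 10.34$, $b = 3.42$ as defaults. `fit_calibration()`
regresses reference pH on ratio — the direction in which the calibration
is applied — and stores the Pearson correlation of the pairs exactly as
supplied, with no replicate averaging first.

Quality gating (`qc_evaluate()`) rejects a reading for exactly one reason,
checked in fixed precedence: high autofluorescence, then low fluorescein
signal, then predicted pH outside [4, 7.5]. The precedence is a package
decision (the method description states the rules but not their order);
autofluorescence comes first because it invalidates the ratio itself
rather than merely weakening it. The thresholds are instrument-relative
because no published values exist: 5% of full scale for autofluorescence
and 1% for the minimum `f520 + f550` signal, where full scale is the DAQ's
10 V range referred back through the gain chain
(`full_scale_signal()` ≈ 90.9 signal units). Replicate triplets that lose
readings to gating are retained with reduced n, and `pooled_sd()`
implements the repeatability metric
$\sqrt{\sum_i (n_i-1) s_i^2 / \sum_i (n_i-1)}$ with singleton groups
excluded.

## Calibration buffers in the simulator

The simulated ratio-to-pH relation is a Möbius transform of the logistic
species fraction, so it is not exactly linear; its shape is controlled by
the relative in-band brightness of the two species. The defaults (dianion
520/35 nm at brightness 1.0, anion 550/45 nm at 0.30, reflecting the
anion's much lower quantum yield) were fixed once so that a linear fit
over the working range behaves like the physical device: overall mean
absolute error below 0.25 pH with the largest bias concentrated in the
4–4.5 band, where the linear fit meets the flattening foot of the curve.

The simulator's default buffer set for fitting that calibration is pH 4.5,
5.5, 6.5, 7.5. With a pure two-species model, a buffer at pH 4.0 sits on
the flat foot of the curve and rotates the fitted line so that the worst
residuals land mid-range instead of at the acid end — the opposite of how
the physical instrument degrades. Anchoring the lowest buffer at 4.5
restores the realistic error profile. `fit_calibration()` itself accepts
any level set, and the tests also exercise the four-level protocol with
ten replicates per buffer and ratio noise of 0.02, recovering the
generating slope within 10%.

## The synthetic cohort generator

No patient-level data are available, so `synth_cohort()` emulates the
study design from its printed summary statistics. Defaults, chosen once:

* Two groups: Pre-Cleaning (7 subjects, 40 surfaces) and Post-Cleaning
  (18 subjects, 45 surfaces); surfaces assigned to subjects round-robin.
* Group diff-pH means 0.84 (Pre) and 0.48 (Post); group rest means 6.65
  and 6.80, set so the surface-weighted rank-0 resting mean is 6.73.
  Carious (rank 1) surfaces, a 0.2 fraction, sit 0.08 pH above sound ones
  at rest. The published summary tables are not mutually consistent (the
  overall rest/drop means imply a smaller mean diff than the group diff
  means); the generator prioritises the rank-0 rest mean and the group
  diff means, so its implied drop means (5.81 / 6.32) differ from the
  printed overall drop value.
* Between-surface SDs of 0.35 (rest) and 0.30 (diff): values in the range
  a clinical box plot of biofilm pH spans, not published constants.
* Replicate noise 0.23 pH — the device's published pooled SD — three
  replicates per phase, readings clipped to [4, 7.5].
* Saliva pH per subject: normal(7.0, 0.2) truncated to [5.5, 8.5]
  (saliva is near-neutral; no distribution is published).

What the generator does *not* emulate: within-subject correlation beyond
shared saliva pH, spatial correlation between adjacent surfaces, missing
readings caused by the actual QC mechanism (missingness is injected by
count, not by simulated autofluorescence), and any drift between rest and
drop sessions. Passing tests therefore demonstrate the statistical
pipeline's calibration and power under idealised independence, not
robustness to those structures.

## The comparison grid

`analyze_cohort()` runs, for each metric (rest, drop, diff = rest − drop)
and each normalisation (raw; divided by the subject's saliva pH —
division, with subtraction available, since the normalised quantity is
described as a quotient), three comparison families: the two cleaning
groups over all surfaces, the groups within each caries rank, and rank 0
vs rank 1 within each group. Every cell gets a two-sided permutation test
on $|\bar a - \bar b|$ (the statistic is a package choice; the source
names the test only). Enumeration is exhaustive whenever
$\binom{n_a+n_b}{n_a} \le 20{,}000$ — with the exact proportion reported,
floating-point ties counted as exceedances — and otherwise 10,000 seeded
shuffles with the add-one estimate $(k+1)/(B+1)$, which cannot return 0.
Welch's t-test (delegated to `stats::t.test`) is reported only when both
samples pass Shapiro-Wilk (`stats::shapiro.test`) at the same alpha,
mirroring the study's treatment of non-normal rank-1 strata; the
significance flag is always driven by the permutation p. Cells with fewer
than two observations per side are skipped with a warning. All permutation
seeds derive deterministically from the single user-facing seed plus the
cell index, so a full analysis is reproducible end to end.

## Imaging

The imaging extension treats a two-channel frame stack (G ≈ 520 nm,
R ≈ 549 nm) as co-registered: `average_frames()` takes the per-pixel mean
of the first n frames (ten frames by default, the published averaging
depth), and `ph_map()` applies per pixel exactly the scalar arithmetic
`(G−R)/(G+R)` then `slope·ratio + intercept` — the constant-image case is
bit-identical to the scalar path. A pixel is invalid when `G+R` falls
below a minimum signal (2% of the image's 99th-percentile total by
default; air bubbles and background) or the pH leaves the calibration
range; invalidity is a mask, never an arithmetic error. `diff_map()`
subtracts on the intersection mask and is antisymmetric there.

The imaging instrument has its own calibration constants (none are
published); `imaging_calibration()` builds one by rendering the forward
model's noiseless ratio at chosen buffer levels and fitting the same
linear family, defaulting to the point-device constants only when the user
supplies none. Noiseless phantom round trips recover the ground-truth
field within 0.05 pH when the calibration is fitted over the field's own
range — the regime in which a local linear fit of the ratio curve is
accurate — and a per-pixel SNR of 10 with ten-frame averaging keeps the
mean absolute error within 0.25 pH. On disk, frame stacks are 16-bit
unsigned TIFF in unit range, and exported pH maps are 32-bit TIFF storing
pH/14 (invalid pixels 0), since the TIFF writer's well-defined domain is
the unit interval.

## Problem sizes and numerical tolerances

The test suite fixes seeds everywhere and uses sizes that make the
statistical assertions sharp without excess: the lock-in oracle compares
against brute-force correlation at 1e-9 on 1 s windows; the noiseless
round trip asserts 1e-9 relative agreement with the closed-form gain; the
type-I-error check runs 500 null cohorts at 599 permutations each
(rejection rate asserted within 0.03–0.07); power under the study effect
uses 100 cohorts at 999 permutations; exhaustive-vs-sampled permutation
agreement is asserted within three binomial standard errors at 10,000
shuffles. Exact-recovery assertions (line fits, pooled SD against its
defining sum) use 1e-10 to 1e-12.

## Known limitations

* Two-species photophysics only; no absorption-spectrum or
  excitation-wavelength modelling, no shot noise, no distance effects.
* The linear calibration family is intentionally simple; a sigmoidal fit
  would remove the acid-end bias but is out of scope, as is any
  autofluorescence-dependent correction of the calibration curve.
* The cohort generator reproduces printed summary statistics, not
  patient-level structure; published clinical p-values are context, not
  targets.
* Frames are assumed co-registered; registration and stitching across
  visits are unsolved for the imaging instrument and excluded here.
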