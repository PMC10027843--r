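---
title: "Models and methods behind nirsarrest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nirsarrest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsarrest)
```

This vignette explains the models the package implements, the choices made
where the methodology was genuinely open, and what the synthetic-data
generator does and does not emulate. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The measurement problem

During sudden cardiac arrest the circulation collapses within seconds.
Invasive arterial pressure shows this almost immediately; a transcutaneous
near-infrared sensor on a muscle sees it indirectly, through the loss of
the cardiac pulsatile component and a slow decline in microvascular oxygen
saturation as the stagnant blood pool is metabolized. The pipeline
quantifies both routes on a common footing: absolute tissue saturation and
relative hemoglobin traces from raw multi-distance attenuation, a simple
first-excursion onset statistic per channel, and a framewise spectral
pulse analysis that works identically on pressure and optical channels.

## Optical model

The sensor is continuous-wave, dual-wavelength (765 and 850 nm), with
three source–detector distances (30, 35, 40 mm) and one photodiode.

**Spatially resolved spectroscopy (SRS).** In the diffusion approximation
for a semi-infinite medium, the spatial slope of attenuation at distances
large compared with the transport length obeys
$\ln 10 \cdot \partial A/\partial \rho = \sqrt{3\,\mu_a \mu_s'} + 2/\bar\rho$.
Per time point and wavelength the package estimates the slope by ordinary
least squares over the three distances, inverts this relation to a
*scaled* absorption $k\,\mu_a(\lambda)$, and solves the 2×2 extinction
system for $k\,[\mathrm{O_2Hb}]$ and $k\,[\mathrm{HHb}]$. The unknown
scattering-dependent scale $k$ cancels in
$\mathrm{TSI} = \mathrm{O_2Hb}/(\mathrm{O_2Hb}+\mathrm{HHb}) \times 100$,
which is why the saturation is absolute while the chromophores are not.

Choices worth recording:

* **Extinction coefficients** are compiled literature values for
  hemoglobin at 765/850 nm, stored in `hb_extinction()` and overridable
  through `optical_geometry()`; commercial devices use proprietary tables,
  so absolute agreement with any particular instrument is not claimed —
  only internal forward/inverse consistency, which the parameter-recovery
  suite checks to 1 % absolute across 40–90 % saturation.
* **Reduced scattering** defaults (9.1 and 8.3 cm⁻¹) are typical of human
  muscle in this window; they scale $k$ only and therefore never move TSI.
* **The DPF** affects only the scaling of the relative (MBLL) chromophore
  units, never the saturation.
* **Negative radicands** (when noise drives the slope term
  $\ln 10 \cdot \partial A/\partial\rho - 2/\bar\rho$ negative) are masked
  as `NA` rather than clipped, and the valid fraction is reported, so
  downstream windows can state their coverage instead of silently
  averaging clipped values.

**Modified Beer–Lambert law.** Relative chromophore changes use a single
distance: $\Delta A(\lambda) = (\varepsilon \cdot \Delta C)\,\rho\,
\mathrm{DPF}(\lambda)$, solved per time point against the mean of a
reference window. `THb` and `Hbdiff` are computed from the recovered
traces so their defining identities hold exactly at every sample.

## Hemodynamics and the onset statistic

MAP is the weighted average systolic/3 + 2·diastolic/3, with systole and
diastole taken as sliding-window extrema (1-s window) rather than by beat
segmentation: extrema stay defined when pulsation vanishes, and in that
limit MAP tends to the instantaneous pressure, which is physically
correct. The extrema trace is then smoothed over the same beat-scale
window — MAP is by definition a per-cycle mean, and the smoothing removes
the plateau distortion sliding extrema impose on slow oscillations such as
ventilation.

Arrest onset per channel is the time from the infusion marker to the first
sample strictly more than $k$ (default 2) baseline standard deviations
beyond the baseline mean, both estimated over the final 60 s before the
marker. Decisions:

* The SD uses the same 60-s window as the mean (only the mean's window is
  canonical; using one window keeps the statistic self-contained), and
  both are recorded in the result.
* `persistence` defaults to 1 — the strict "first drop" reading — but is
  exposed because a single-sample rule is noise-sensitive; the test suite
  exercises both.
* Ties exactly at the threshold do not trigger (strict inequality).
* A zero-variance baseline is an explicit error, not a latency.

## Pulse rate and amplitude

The STFT uses fs = 10 Hz, 528-sample frames, 24 % overlap — i.e. a hop of
`round(528 × 0.76) = 401` samples — and a fixed Hann taper (the taper is
not canonical; fixing it makes results reproducible). Partial trailing
frames are dropped, so a 60-s window at 10 Hz contains exactly one full
frame; confidence intervals are therefore 0 for single-frame windows, and
multi-frame behaviour is exercised on longer traces in the tests. The
one-sided power scale is amplitude-calibrated (a unit-variance sinusoid
lands at its time-domain power), so after z-scoring the dB amplitudes of
different channels share the only meaningful reference: the unit variance
of the normalized input.

**Silence floor.** The dominant in-band bin of pure noise is never
literally absent, so pulselessness needs a floor. The floor is a margin
above the frame's median broadband power. For roughly 200 one-sided bins
of white noise the periodogram powers are approximately scaled
$\chi^2_2$; the expected maximum-to-median ratio is then
$\ln(200)/\ln 2 \approx 7.6\times$ (~9 dB), so a 6-dB margin would declare
noise-only frames pulsed essentially always. The default margin is 12 dB:
above the noise-maximum expectation, far below any real pulse peak, which
sits orders of magnitude above the broadband median after z-scoring.

## Statistical battery

* **D'Agostino–Pearson omnibus K²** is implemented from the standard
  normalizing transformations of sample skewness and kurtosis (no
  installed R package provides it); it is checked in the tests against
  values computed with an independent reference implementation, agrees to
  ~1e-10, and refuses n < 8, where the χ² approximation is invalid.
* **Paired/unpaired t-tests** delegate to `stats::t.test`. Identical
  paired samples return t = 0, p = 1 (no difference at all); a *nonzero*
  constant difference is degenerate and errors. The one-tailed p is
  carried alongside the two-tailed default because published directional
  contrasts are sometimes one-tailed: re-computing the PO₂
  baseline-vs-euthanasia contrast on the bundled reference values gives a
  two-tailed p of 0.0055 and a one-tailed p of 0.0028, and the package
  reports both rather than forcing agreement with either convention.
* **Repeated-measures ANOVA** uses the subject-stratified
  `aov(value ~ condition + Error(subject))`; the two-condition case is
  verified against the squared paired-t identity. Post-hoc pairwise
  comparisons use the **Holm–Šídák** step-down adjustment (implemented
  here; `p.adjust` offers Holm but not Šídák step-down), and the method
  name is always printed beside adjusted p-values because "adjusted"
  alone is ambiguous.

## The synthetic physiology generator

The generator's defaults are the study conditions: eight ventilated
miniature pigs, infusion marker at 600 s, 10 min of baseline and 5 min of
post-arrest capture. Per animal it simulates:

* **ABP** (10 or 100 Hz): rectified-sinusoid beats between the diastolic
  and systolic baselines — sufficient for extrema-based MAP and for
  spectral analysis, where only the fundamental matters; a richer
  waveform (dicrotic notch etc.) is deliberately out of scope. After the
  marker plus a circulation lag, mean pressure and pulse envelope decay
  exponentially; residual low-amplitude pulsation (10 % of baseline,
  default 8 min, motivated by the published 5.5–16 min range of
  post-mortem cardiac activity) rides on the collapsed pressure.
* **Optics** (10 Hz): latent chromophores at constant total hemoglobin
  (60 µM), saturation decaying from baseline with τ = 120 s, converted to
  attenuation by the same forward model the analysis inverts, plus a
  cardiac O₂Hb pulsatile component (0.4 µM) tracking the arterial
  envelope, optical-density noise, and the shared artifacts. The stream
  runs on its own clock with a configurable offset.
* **PO₂** (1 Hz): flat until the marker plus a long lag (hemoglobin
  buffers the dissolved-oxygen pool), then exponential decay to
  ~0.5 mmHg.

**Respiration is the backbone of baseline variability.** All channels
carry a ventilator oscillation (default 0.18 Hz ≈ 11 breaths/min) whose
amplitude dominates the baseline SD, plus small white measurement noise.
This structure is what makes a strict single-sample 2-SD rule usable at
all: a bounded sinusoid never reaches twice the total SD on its own,
whereas Gaussian white noise of the same total SD would cross a 2-SD
threshold within seconds at 10 Hz ($\Phi(-2) \cdot f_s \approx 0.23$
crossings per second). Real recordings behave like the former. The
respiratory amplitude collapses with the pulse envelope after arrest —
pressure transmission requires circulation.

**Calibration of defaults.** The decay constants and onset lags are free
parameters of the model (the published record shows collapse shapes only
in figures) with defaults calibrated once to the printed summary
latencies: `tau_map` is derived per config so the noiseless MAP falls
below 5 mmHg 52.6 s after the marker (the canine collapse time the
original report cites); the channel lags (9.5 s MAP, 7 s TSI, 24 s PO₂)
place the noiseless 2-SD crossings near the published 10.4 / 12.0 /
25.0-s latencies; the saturation drop depth is calibrated so the mean over
the last 10 s of the post window equals `tsi_drop` exactly. The `"reference"`
cohort preset pins per-animal baselines, drops, heart rates, and
post-arrest MAP floors to the printed per-animal values, and flags the
channels missing in the original cohort (n = 7 MAP, 6 PO₂, 8 TSI).

**Artifacts and alignment.** Motion artifacts are shared biphasic
transients (derivative-of-Gaussian, 0.5-s width) injected into the
pressure and optical streams at scheduled times, large compared with the
physiological signal — which is precisely what makes them usable as
alignment fiducials. Alignment proceeds in two stages: a coarse
normalized cross-correlation of clipped artifact-band envelopes (the
envelope, not the waveform, because both streams share the same heart and
waveform correlation peaks at every beat period; the high-pass corner,
0.4 Hz, sits above ventilation rates for the same reason), then
refinement by matching the individual artifact-burst centres
(sub-sample parabolic interpolation, median over matched events) — an
automated version of matching artifact patterns by eye. Filter edge
transients are blanked before correlation because both arrays carry them
at their own boundaries, where they would correlate at zero lag. A peak
below the confidence floor raises an "ambiguous" error rather than
returning a guess.

**Ground truth.** Per channel the truth table records the first crossing
of the noiseless trajectory — deterministic decay *plus* the equally
deterministic respiratory oscillation, whose phase is reproducible from
the channel seed — below baseline − 2·SD, scanned on the channel's own
grid. Defining truth on the respiration-inclusive trace matters: the
detector legitimately fires at respiratory troughs, which is signal, not
noise.

**What the generator does not emulate**, and hence what passing tests do
not show about real data: beat-to-beat and respiratory *variability*
(rates are constant), waveform morphology (dicrotic notch, reflected
waves), drifting baselines, skin-pigmentation and adipose-layer optics,
probe-placement variation, non-Gaussian artifact families, and
respiratory-arrest physiology (the generator models primary cardiac
arrest under continued ventilation only).

## Numerical conventions

* Time windows are half-open `[from, to)` with a half-sample tolerance so
  grid round-off never drops an endpoint.
* Resampling: linear interpolation upward; zero-phase Butterworth
  low-pass at 0.45× the target rate before downsampling, so detection
  timing is not skewed by filter delay.
* Degenerate inputs error loudly and name the offending field: zero
  baseline SD, markers outside the recording, saturation trajectories
  leaving (0, 100), non-increasing distances, singular extinction
  matrices.
* Problem sizes in the test suite (20-animal cohorts for detection
  recovery, 50 alignment trials, 100-seed null calibration of the
  normality test) were chosen as the smallest sizes at which the
  stochastic acceptance properties are stable.

## Known limitations

Absolute TSI agreement with any commercial instrument is out of reach
(proprietary scattering corrections and extinction tables); the package
claims internal consistency only. The single-frame 60-s STFT window
reports zero-width confidence intervals by construction. The residual
post-mortem pulsation is a real in-band tone, so a default-configured
animal shows a nonzero post-euthanasia pulse rate unless the residual
activity has ended before the analysis window — reporting it is a
feature of the detector, not a bug of the simulation.
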