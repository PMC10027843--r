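# nirsarrest

Analysis pipeline for detecting cardiac arrest in multi-channel
physiological recordings that pair **transcutaneous near-infrared
spectroscopy (NIRS)** with invasive arterial blood pressure (ABP) and
tissue PO₂ monitoring, plus a synthetic physiology generator that emulates
a porcine euthanasia experiment (pentobarbital-induced primary cardiac
arrest under mechanical ventilation) with full ground truth.

The package is aimed at researchers developing wearable optical sensors
for out-of-hospital sudden-cardiac-arrest detection: it provides the full
chain from raw multi-distance optical attenuation to cohort-level
statistics, and a simulator realistic enough to power parameter-recovery
tests of every stage.

## What it computes

**Optics.** A continuous-wave, dual-wavelength (765/850 nm) sensor with
three source–detector distances (30/35/40 mm) in a spatially resolved
spectroscopy (SRS) configuration. Per time point and wavelength the
attenuation-vs-distance slope gives a scattering-corrected absorption

&nbsp;&nbsp;&nbsp;&nbsp;k·μₐ(λ) = (ln10 · ∂A/∂ρ − 2/ρ̄)² / (3 μs′(λ)),

the 2×2 extinction system yields k·[O₂Hb] and k·[HHb], and the unknown
scale k cancels in the **tissue saturation index**

&nbsp;&nbsp;&nbsp;&nbsp;TSI% = [O₂Hb] / ([O₂Hb] + [HHb]) × 100.

Relative chromophore traces (ΔO₂Hb, ΔHHb, THb = O₂Hb+HHb,
Hbdiff = O₂Hb−HHb) come from the modified Beer–Lambert law at a single
distance. A matching forward model (`forward_attenuation()`) makes the
inversion testable end-to-end.

**Hemodynamics.** MAP = systolic/3 + 2·diastolic/3 from sliding-window
waveform extrema; baseline (60 s pre-infusion) vs euthanasia (last 10 s of
the 5-min post window) summaries with cohort Mean/SD rows.

**Detection.** Arrest onset per channel as the latency from the infusion
marker to the first sample two standard deviations below the 60-s
pre-infusion baseline (`first_change_time()`), with per-channel latency
tables and paired comparisons.

**Pulse.** Short-time Fourier transform (fs = 10 Hz, 528-sample FFT, 24 %
overlap, Hann taper) of z-score-normalized ABP and O₂Hb; per-frame
dominant in-band frequency (0.5–4 Hz) gives the pulse rate, with a silence
floor so pulseless segments report 0; in-band peak power in dB gives the
pulse amplitude.

**Statistics.** D'Agostino–Pearson omnibus normality screen, paired and
unpaired Student's t-tests, one-way repeated-measures ANOVA with
Holm–Šídák-adjusted post-hoc comparisons, and a CSV/figure report bundle.

## Worked example

```r
library(nirsarrest)

cfg <- animal_config(animal_id = "pig01", seed = 42)  # defaults = study conditions
sim <- simulate_animal(cfg)     # ABP @100 Hz, optics @10 Hz, PO2 @1 Hz + truth
res <- analyze_animal(sim)      # align, invert optics, detect, pulse analysis

res$summaries
#>   channel baseline_mean post_value delta
#> 1 MAP              79.6     -0.180 -79.7
#> 2 TSI              67.2     52.7   -14.5
#> 3 PO2              38.7      0.468 -38.3

res$detections[, c("channel", "latency", "threshold")]
#>   channel latency threshold
#> 1 MAP        10.6      70.6
#> 2 TSI        12.2      65.7
#> 3 PO2        24.8      37.8

res$pulse[, c("window", "channel", "rate_hz", "amp_db")]
#>   window channel rate_hz amp_db
#> 1 pre    ABP        1.69  -1.67
#> 2 pre    O2Hb       1.69 -16.8
#> 3 during ABP        2.16 -15.2
#> 4 during O2Hb       0    -29.3
#> 5 post   ABP        1.69 -21.6
#> 6 post   O2Hb       0    -32.3
```

Reading the output: the simulated animal's saturation drops 14.5 % over
the five minutes after the infusion marker while MAP collapses to the
static floor; MAP crosses its 2-SD detection threshold 10.6 s after the
marker, the optical saturation 12.2 s after it, and the (slow, buffered)
tissue PO₂ only at 24.8 s. Pre-arrest both the pressure- and the
NIRS-derived channel report the same 1.69-Hz pulse; the transient
tachycardia raises the rate in the first post-infusion minute; pressure
pulse amplitudes are consistently stronger than the optically derived
ones, and both collapse after arrest. A cohort version of all of this —
including the per-channel Mean/SD table and the t-test battery — comes
from `analyze_cohort(simulate_cohort(8, preset = "reference"))`.

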