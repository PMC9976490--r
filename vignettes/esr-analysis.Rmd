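---
title: "Models and methods behind esrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind esrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esrkit)
```

## The signal and the problem

During epidural electrical stimulation (EES) of the spinal cord, the
non-stimulating contacts of the implanted leads record an epidural spinal
recording (ESR) that superimposes several sources:

* the **ECAP** — the evoked compound action potential of synchronously
  recruited dorsal-column axons. It *travels*: its negative peak (N1) reaches
  a contact at `onset + distance / velocity`, it shrinks with distance from
  the stimulation site, and it recruits sigmoidally with stimulation current;
* the **stimulation artifact** — capacitive/resistive pickup of the pulse
  itself, time-locked to the pulse with *zero* inter-contact delay;
* an **EMG component** — myogenic potential from stimulation-evoked
  contraction of nearby (e.g. intercostal, paravertebral) muscles. It appears
  essentially simultaneously on all contacts, i.e. it is a common-mode
  component, and it recruits at a higher current than the ECAP;
* noise (white, line hum, occasionally cardiac deflections).

Everything the package does follows from this decomposition: referencing
schemes trade off how much of each common-mode component survives;
conduction velocity identifies the neural component and its fiber class; the
propagation test tells a travelling component from a simultaneous one; and
between-session changes in ECAP latency and magnitude reveal lead migration.

## The synthetic-data generator

No public recordings of this kind exist, so the package ships a generator
(`simulate_session()`) that produces sessions with exactly the statistical
structure above, for two 8-contact leads (3 mm contacts, 4 mm gaps, 7 mm
pitch; stimulating pair 7/8) plus a tissue reference electrode, sampled at
25 kHz. The stimulation waveform is the charge-balanced asymmetric pulse
(400 us anodic then 80 us cathodic at five times the amplitude, so
0.48 ms total) delivered at 38 Hz, with a 1.3 ms pre-stimulus lead-in per
epoch.

Key modelling choices:

* **ECAP template.** Published figures show the morphology but no analytic
  form, so the template is parametric: a central negative Gaussian with two
  smaller positive lobes at ±2.5 widths (P1–N1–P2), unit negative peak,
  default width 0.12 ms. Peak times are resolved at sample resolution
  (0.04 ms), with no sub-sample interpolation — adequate because the
  0.1 ms adjacent-contact delay at 70 m/s spans 2–3 samples.
* **Attenuation.** Axial attenuation is a single exponential; the
  medio-lateral offset enters only as a Gaussian coupling gain
  (`exp(-x^2 / (2 * 5^2))`), not as extra path length, because lateral lead
  shifts are reported to leave ECAP latency unchanged. Neither decay constant
  is measurable from published data, so both are free parameters. The axial
  default (11 mm) was calibrated once so that the full analysis pipeline
  (component windows, 5-trial grouped medians, realistic noise) reports a
  ≈24% magnitude drop for a 3.5 mm rostro-caudal shift — the size of effect
  reported for postural lead displacement — and it is deliberately the model's
  strongest simplification: a single exponential cannot simultaneously show
  that sensitivity and keep the ECAP visible 100 mm away, as real recordings
  do. Suites that need usable SNR on all eight recording channels therefore
  park the recording lead alongside the stimulation lead
  (`recording_offset_mm`, side-by-side lateral tracks), which is also the
  arrangement used for the conduction-velocity recovery checks.
* **Recruitment.** A gated logistic: exactly zero below threshold,
  `1 / (1 + exp(-(I - thr) / slope))` above. Defaults: ECAP threshold 1.2 mA;
  EMG threshold 1.56 × that, the mean EMG/ECAP threshold ratio across the
  published cohort (`threshold_summary()`).
* **EMG burst.** A 300 Hz carrier under a Gaussian envelope centred
  7.5 ms after the pulse end (onset 3.5 ms, nominal duration 8 ms), identical
  on all contacts up to a 2% fixed gain jitter, with a large (0.5) pickup on
  the reference electrode, which sits in muscle. The envelope's leading tail
  is what spills into the ECAP window at high currents; a single-source burst
  cannot reproduce the *apparent* conduction delay that multiple
  asynchronous muscles can create under LTR — noted, not modelled.
* **Artifact.** The pulse convolved with an exponential electrode/tissue
  impulse response (τ = 0.08 ms), gain decaying with a 40 mm constant — a
  far-field signal falls off much more gently than the ECAP — and a small
  (0.02) reference pickup.
* **Reference electrode.** Picks up artifact and EMG but *zero* ECAP: it sits
  in non-neural tissue.
* **Reproducibility.** All randomness (noise, gain jitter) derives from the
  `seed` argument; potentials are quantized to IEEE single precision, the
  on-disk storage format, so a session survives a write/read round trip bit
  for bit.

What passing tests on this generator do **not** show: robustness to real
electrode impedance drift, non-exponential attenuation, multi-muscle EMG
timing, or vendor acquisition quirks. They do show that the algebra, the
estimators and the decision rules are correct under the stated model.

## Referencing

`apply_reference()` implements pure subtraction algebra (no filtering):
LTR subtracts the tissue reference; DIFF subtracts the next more caudal
contact on the same lead (the published usage "using channel 2 and recording
from channel 1" fixes that direction); REFk subtracts a designated contact.
Because every scheme is a difference of the same potentials,
`REFk(i) = LTR(i) - LTR(k)` exactly, and an on-lead reference injects the
additive inverse of its own ECAP into every trace — the origin of the extra
inflection and of the collapsed apparent conduction delay near the reference
contact (REF9), and of the polarity flip around contact 3 (REF3).

## Filters and averaging

The standard offline pair is a first-order 100 Hz Butterworth high-pass and
a Gaussian low-pass that is −3 dB at 3 kHz. The high-pass is run causally
(forward only): onsets stay causal, and its constant delay cancels in every
between-channel difference (conduction velocity, propagation test). Whether
the reference processing was zero-phase is unstated; this choice is
documented, not inferred. The Gaussian kernel has
σ = sqrt(ln 2) / (2π f_c), truncated at ±4σ, with replicate padding at epoch
edges; filtering happens after referencing. Robust averaging is the
per-sample median of groups of 5 consecutive trials (`median_waveform()`),
300 trials → 60 grouped medians; the published analyses retain 40 after a
visual exclusion step that is not reproducible and is therefore not
modelled.

## Windows and features

All component windows live in ms **after the end of the stimulation pulse**
(0.48 ms after onset): ECAP 0.33–1.80, EMG 1.8–13, EMG-AUC 3.5–9. The
0.33 ms gap doubles as the artifact blanking margin — the published
"end of the stimulation artifact" criterion is visual, so it is
operationalized as pulse end + a configurable margin. An alternative ECAP
preset (2.1–5 ms in recording coordinates, for an epoch starting 1.3 ms
before the pulse) is carried verbatim: the two published ECAP windows use
different origins and extents and are *both* provided, unreconciled.
Features per trace: negative-peak latency (from pulse end; ties to the
earlier sample; an all-positive window returns a `no_negative_peak` flag),
peak-to-peak, and AUC as the plain absolute-value sum × dt (no trapezoid),
optionally divided by the stimulation amplitude in mA — the normalization
wording is ambiguous, so division by the cathodic amplitude was chosen.

Conduction velocity is the inverse OLS slope of peak time on contact
distance (≥3 channels, flagged channels excluded; slope ≤ 0 →
"non-propagating"). Fiber classes follow the printed half-open ranges
(Aδ [5, 35), Aβ [35, 80), Aα [80, 120]); 72.29 m/s is classified Aβ by
those ranges even though it is sometimes described as borderline. Detection
thresholds take the smallest amplitude whose window AUC exceeds the
pre-stimulus baseline mean + 3 SD *with every larger amplitude also
exceeding it*, so a single noisy excursion cannot define a threshold.

## Component discrimination

`propagation_test()` regresses per-channel peak times on distance and
classifies by the slope CI rather than a fixed delay cutoff: *propagating*
when the CI excludes zero and the implied velocity is physiological
(5–120 m/s), *common-mode* when the CI contains zero, *indeterminate*
otherwise (e.g. an apparent 500 m/s). `flag_spillover()` combines an
EMG-presence criterion (EMG-window AUC above the pooled pre-stimulus noise
criterion) with a failed propagation test inside the ECAP window. The
pre-stimulus noise is pooled across channels because one 1.3 ms lead-in is
too short for a stable per-channel SD.

## Migration detection

`compare_sessions()` takes per-grouped-median features from two sessions at
comparable amplitudes. Latency is compared with a Welch t-test gated by
Shapiro–Wilk (rank fallback when either sample is clearly non-normal;
degenerate constant samples short-circuit to p = 1 or 0). The percent change
in amplitude-normalized AUC gets a bootstrap SD and two-sided p (1000
seeded resamples). The migration flag requires a change that is both
significant at α and above a magnitude floor — 0.08 ms (two samples) for
latency, 20% for AUC — so statistics alone cannot flag at huge n. Direction
hints: significant latency increase + AUC decrease is rostro-caudal
consistent; significant AUC change with stable latency is the amplitude-only
signature of lateral shifts. Whether published comparisons used per-trial or
per-median values is unstated; grouped medians were chosen and are the unit
everywhere.

## Problem sizes and numerical choices in the test suite

The suites are sized to run quickly while keeping their statistical meaning:
type-I error of the propagation test over 500 common-mode sessions (10
pulses each), migration false alarms over 200 identical-configuration pairs
(25 pulses, 5 grouped medians each), dose-response sweeps of 36 amplitudes ×
10 pulses, and velocity recovery with 200 trials → 40 grouped medians per
velocity. The noisy velocity-recovery suite uses a wider custom window
(0.33–2.6 ms) and a nearer lead so that the N1 peak stays inside the window
across the whole 35–80 m/s range — with the default window an 80 m/s peak on
the nearest contact would land before the window opens and a 35 m/s peak on
the farthest contact after it closes, which clips peaks and biases the
slope. Degenerate inputs are handled explicitly: zero-residual regressions
collapse the CI to a point; constant samples bypass Shapiro–Wilk; bootstrap
p-values are floored at 2/(B+1).

## Known limitations

Single-exponential attenuation (see above); single-source EMG; no
volume-conductor field model; ideal sampling (no hardware anti-aliasing
model); latency at sample resolution; simulated trial-to-trial variability
comes from noise only, while component shapes repeat exactly across pulses
of the same amplitude.
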