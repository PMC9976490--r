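# esrkit

Analysis of **epidural spinal recordings (ESR)** made during epidural
electrical stimulation (EES) of the spinal cord, for researchers and
engineers working on stimulation-evoked sensing: ECAP extraction, virtual
re-referencing, conduction-velocity estimation, EMG-spillover discrimination
and lead-migration detection — plus a synthetic-session generator, because
recordings of this kind are proprietary and none are publicly available.

## The signal model

A multi-contact epidural lead records, per stimulation pulse, the
superposition

* **ECAP** — the evoked compound action potential of recruited dorsal-column
  axons. Its N1 (largest negative) peak arrives at contact *i* at
  `t_i = t0 + d_i / v`, where `d_i` is the stimulation-recording distance and
  `v` the conduction velocity (Aδ 5–35, Aβ 35–80, Aα 80–120 m/s); its
  amplitude decays with distance and recruits sigmoidally above a current
  threshold.
* **Stimulation artifact** and **EMG** (evoked contraction of nearby
  muscles) — *common-mode* components with zero inter-contact delay.
* Noise.

The core quantities the package computes:

* latency (pulse end → N1 peak), peak-to-peak, and AUC
  (`Σ|x_i|·dt`) inside standard component windows (ECAP 0.33–1.80 ms,
  EMG 1.8–13 ms, EMG-AUC 3.5–9 ms after pulse end);
* conduction velocity as the inverse OLS slope of N1 time on contact
  distance, `v = 1/β̂`, with r² and fiber classification;
* referencing algebra `LTR(i) = V_i − V_ref`, `DIFF(i) = V_i − V_caudal(i)`,
  `REFk(i) = V_i − V_k` (so `REFk(i) = LTR(i) − LTR(k)` exactly);
* a propagation verdict from the CI of the latency–distance slope
  (propagating / common-mode / indeterminate), used to flag EMG spillover
  into the ECAP window;
* between-session comparison of latency and normalized AUC (t-test /
  bootstrap, magnitude floors) that raises a lead-migration flag with a
  direction hint.

## Worked example

Simulate a session (two 8-contact leads, recording lead alongside the
stimulation lead with its nearest contact 30 mm away; 50 pulses at 1.8 mA —
just under the EMG threshold, where the ECAP is clean), re-reference,
filter, average, and estimate the conduction velocity:

```r
library(esrkit)

geometry <- lead_geometry(recording_offset_mm = 30, lateral_offset_mm = c(0, 1))
protocol <- stim_protocol(amplitude_mA = 1.8, pulses_per_amplitude = 50)
session  <- simulate_session(geometry, protocol,
                             ecap = ecap_source(velocity_m_per_s = 72.29),
                             seed = 42)
session
#> <esr_session 'session'> 17 electrodes x 33715 samples @ 25000 Hz, 50 stimulation events

epochs  <- bandpass_epochs(apply_reference(epoch_session(session), "LTR"))
medians <- median_waveform(epochs, group_size = 5)   # 50 trials -> 10 medians

# contacts where the ECAP stays clearly above the noise floor
features <- extract_features(medians, channels = 12:16)
cv <- estimate_cv(features)
cv
#> <esr_cv> 71.14 m/s (Abeta), r^2 = 0.960, n = 50
```

The estimator recovers the configured 72.29 m/s within a few percent under
5 µV noise (and within 1% when noiseless); the velocity falls in the Aβ-fiber
range, as expected for dorsal-column recruitment. Detecting a lead shift:

```r
shifted   <- shift_lead(geometry, 2, delta_rostral_mm = 3.5)
session2  <- simulate_session(shifted, protocol,
                              ecap = ecap_source(velocity_m_per_s = 72.29),
                              seed = 43)
f2 <- extract_features(median_waveform(bandpass_epochs(
        apply_reference(epoch_session(session2), "LTR")), 5), channels = 16)

compare_sessions(extract_features(medians, channels = 16), f2)
#> <esr_migration> MIGRATION FLAGGED (hint: rostro-caudal-consistent)
#>   latency: +0.044 ms (sd 0.013), p = 2.43e-05 [wilcoxon]
#>   AUC: -27.8% (boot sd 0.5), p = 0.002
```

A 3.5 mm rostral shift of the recording lead — the displacement expected
from a posture change — lengthens the conduction path (latency up) and
weakens the coupling (AUC down), the rostro-caudal migration signature.
`threshold_summary()` reproduces the cohort threshold arithmetic: the EMG
detection threshold exceeds the ECAP threshold by 56% on average
(`mean_excess_pct = 55.9`).

Each result type has `tidy()` / `glance()` methods and an `autoplot()`.

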