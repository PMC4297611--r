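# ichseizr

Seizure detection and quantification for two-channel telemetry EEG in rat
models of intracerebral hemorrhage (ICH).

Acute electrographic seizures are a common complication of ICH. In the rat,
collagenase infusion into the striatum (which erodes vessels and bleeds over
hours) provokes seizures in a majority of animals within the first
~10–36 h, while autologous blood infusion of comparable lesion size does
not — a contrast with direct consequences for model selection in
neuroprotection studies. Quantifying that contrast from week-long
two-channel (ipsilateral/contralateral) telemetry recordings requires a
chain of signal-analysis steps; `ichseizr` implements that chain as a
tested, reproducible package for electrophysiologists working with rodent
telemetry EEG.

What it computes:

* **Amplitude**: RMS, event/baseline RMS ratios, per-day RMS fold changes,
  and empirical 95% amplitude intervals of normal activity.
* **Spectra**: Welch power spectral density (6-s Hann windows, 2-s
  overlap; mV²/Hz) with chi-squared 95% CIs; affected-band calling and
  band-integrated power change (mV²) of ictal traces against
  duration-matched baseline.
* **Coherence**: magnitude-squared coherence `C(f) = |S_xy|² / (S_xx S_yy)`
  (3-s windows, 1-s overlap) between hemispheres, with significance from a
  randomized null built by sequential circular time shifts (and time
  reversals) of one channel. The null's 95% confidence limit follows the
  analytic independent-segment quantile `1 − 0.05^(1/(K−1))`: ≈0.22 for
  27-s traces (K = 13) down to ≈0.061–0.069 for 87-s traces (K = 43).
  Coherence increases at or above the limit are significant (one-sided).
* **Events**: automated ictal delimitation by baseline-referenced sliding
  RMS with laterality classification; interictal spike detection at 3.5
  baseline SD with average waveform and rate per minute.
* **Cohort**: per-subject summary rows (incidence, laterality, total
  duration as "total (mean ± SD)", onset latency as "H h, M min", RMS
  ratio, power increase, coherence change), two-sided Fisher exact
  incidence test, Mann-Whitney U, lesion volumetry from serial section
  areas, and peri-event temperature/activity deltas.
* **Synthetic data**: a two-channel generator with exact ground truth
  (behavioral-state background, drifting ictal bursts with postictal
  suppression, downward biphasic spikes, controllable cross-channel
  coupling) emulating the study conditions, so the whole pipeline is
  testable without animal data.

## Worked example

Coherence of an 87-s independent two-channel background and its surrogate
null:

```r
library(ichseizr)
bg <- generate_background(synth_config(duration_s = 87, states = "awake", seed = 1))
ep <- extract_epoch(bg$recording, "both", 0, 87)
msc(ep)
#> <coherence_estimate> 751 bins, 0-250.0 Hz, 43 segments (3 s window, 1 s overlap)
#>   mean coherence 0.0222 (1/K bias floor 0.0233)
surrogate_null(ep)
#> <coherence_null> 56 surrogates (28 shifts + reversals), K = 43 segments
#>   95% confidence limit (pooled, 0-100 Hz): 0.0689  [analytic iid: 0.0688]
```

The mean coherence of independent channels sits at the estimator's 1/K
bias floor, and the randomized-null confidence limit matches the analytic
quantile — any event/baseline coherence increase of at least 0.0689 on
such a trace would be called significant.

Detecting two injected seizures (37 s and 65 s, amplitude gain 4) on a
state-mixed background with a 5-min baseline epoch:

```r
ev <- detect_ictal_events(rec, baseline_stats(rec, 0, 300),
                          baseline_window = c(0, 300))
ev
#> <ictal_events> 2 event(s)
#>  subject_id onset_s offset_s duration_s onset_latency_h laterality
#>          S1   309.9    347.1      37.15         0.08609  bilateral
#>          S1   371.7    437.0      65.32         0.10324  bilateral
#>  rms_ratio_ipsi rms_ratio_contra suppression_ratio
#>           3.973            3.964            0.1717
#>           3.970            3.972            0.1632
```

Onsets and offsets are recovered to well under a second, RMS ratios match
the injected gain, and the postictal suppression descriptor shows the
amplitude collapse after each burst.

A full cohort run — generate, detect, characterize, summarize, compare:

```r
report <- run_pipeline(pipeline_config(), out_dir = "out", quiet = TRUE)
report
#> <ich_report> 15 subject(s), 32 event(s) [18.5 s]
#>             seizure no_seizure
#> collagenase       6          3
#> blood             0          6
#> Fisher exact p (incidence): 0.0278
#> Mann-Whitney counts: U = 45, p = 0.0167; total duration: U = 45, p = 0.0167
#> Mean lesion volume (mm^3): blood 39.9, collagenase 34.6
```

Six of nine collagenase subjects seize and no blood subject does, giving
the exact two-sided incidence p of 0.0278 (printed as 0.028 at three
decimals); U = 45 is the maximal rank separation for 9-vs-6 groups. The
`out/` directory receives `events.tsv`, `summary.tsv` (the per-rat table),
`cohort_stats.tsv`, `lesions.tsv`, and a JSON manifest; re-running with
the same configuration reproduces every table byte for byte. The same run
is available from a shell via `inst/cli/ichseizr analyze --out-dir out`.

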