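---
title: "Quantifying electrographic seizures in two-channel rodent telemetry EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying electrographic seizures in two-channel rodent telemetry EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ichseizr)
```

`ichseizr` quantifies electrographic seizure activity in continuous
two-channel (ipsilateral/contralateral) telemetry EEG from rat models of
striatal intracerebral hemorrhage (ICH), where collagenase infusion — but
not autologous blood infusion — provokes acute seizures. The package covers
the complete analysis chain: amplitude (RMS) measures referenced to
non-epileptic baseline, Welch power spectra with confidence intervals,
cross-hemispheric coherence tested against a randomized surrogate null,
automated ictal event delimitation with laterality, amplitude-threshold
interictal spike detection, per-subject summaries, lesion volumetry,
peri-event telemetry deltas, and cohort statistics. Because no public
recordings exist for this preparation, a synthetic generator with exact
ground truth stands in for the animals; every stage is validated against
that truth.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic validation does and
does not establish about real data.

## The signal model behind the generator

**Background.** Two channels of state-dependent, spectrally shaped Gaussian
noise at 500 Hz (the telemetry probe's rate; acquisition hardware low-passes
at 100 Hz, treated as a property of the data). Each behavioral state has a
power-law spectrum $S(f)\propto f^{-\alpha}$ flattened below 1 Hz:

* awake: $\alpha = 2.5$, RMS 0.1 mV — low amplitude, relatively fast;
* slow-wave sleep (SWS): the same base with a 12-fold power boost in the
  0.5–4 Hz delta band and RMS 0.25 mV — the high-amplitude delta picture of
  rodent sleep.

States alternate deterministically (60 s awake / 40 s SWS by default) with
0.2-s crossfades. The slope default deserves a note: published rodent EEG
spectral slopes run roughly $f^{-2}$ to $f^{-3}$, and the choice also
preserves a property that amplitude-threshold spike detection presupposes —
normal background essentially never crosses 3.5 SD (measured: well under one
spurious crossing event per minute; by the Rice level-crossing rate, a flat
$1/f$ spectrum over the full 0.5–100 Hz band would instead cross ~5–8
times/min and make the classical 3.5-SD detector meaningless on its own
normal traces).

**Coupling.** A shared-component fraction $c\in[0,1]$ mixes a common series
into both channels, $x_i = \sqrt{c}\,s + \sqrt{1-c}\,n_i$, giving true
magnitude-squared coherence $c^2$ at every frequency: an analytic handle
for validating the coherence stack (cohort default $c = 0.3$, i.e. MSC
0.09, weak physiological interhemispheric coupling).

**Ictal events.** An amplitude-modulated sinusoid whose frequency drifts
linearly (default 8 → 4 Hz, a tonic–clonic-like slowing), with 0.5-s
raised-cosine edges, followed by multiplicative postictal suppression
(default factor 0.3 for 10 s). The oscillation amplitude is solved so the
*total* RMS over the event equals `amplitude_gain` times a reference RMS.
By default the reference is the local pre-injection background (so gain 1
is exactly a no-op); cohort fixtures pass the subject's baseline-epoch RMS
instead, which makes the injected gain numerically equal to the tabulated
"RMS ratio" (event RMS / non-epileptic RMS) whatever behavioral state the
event lands on. The injected difference series is stored, so background
restoration is exact — the additivity invariant tests rely on this.

**Interictal spikes.** Biphasic transients, dominant negative ("downward")
phase, 80 ms wide, amplitude in units of the local background SD (default
5), at Poisson times with a refractory floor or at an exact count. Truth
records peak times. Note one deliberate subtlety: injected peaks are
exactly 5 SD, but on the realized trace the additive background
occasionally cancels a peak below 3.5 SD, so recovery is asserted on rates,
not on every individual spike.

**Cohort.** Defaults encode the emulated study conditions: 9 collagenase
subjects (6 with seizures; per-subject event counts 1, 2, 3, 4, 8, 14;
first onsets uniform in 10–36 h post injection; durations uniform in
5–90 s; one subject purely ipsilateral) and 6 blood subjects with none.
Two seizing subjects receive interictal spikes at ~20 and ~10/min.
Recordings are desk-scale: a 300-s event-free head (the 5-min baseline
epoch convention) plus the events, padded to whole state cycles with an
event-free final cycle; `t0` places the window at the true latency.
Histology fixtures are serial section areas constructed so the volumetric
formula recovers the intended deficit exactly (group means 32.5 and
40.9 mm³, SD 8 mm³ — realistic magnitudes for moderate striatal ICH).

## Spectral estimation

`welch_psd()` implements the averaged modified periodogram: 6-s Hann
windows, 2-s overlap, per-segment mean removal, one-sided density in
mV²/Hz at 1/6-Hz resolution. Parseval consistency (integral = variance
within 2% on stationary noise) is enforced by test. The per-bin 95% CI is
the classical chi-squared interval of the Welch mean with equivalent
degrees of freedom $2K$ for $K$ segments. We considered the percentile
spread of the individual segment periodograms instead, but periodogram
ordinates are approximately exponential, so that interval's lower edge
sits near zero regardless of the data and can never call a power increase
significant; the chi-squared interval of the *estimate* is the
deterministic, field-standard construction that supports band calling.

`power_increase()` compares an ictal spectrum against a duration-matched
baseline spectrum: a bin is affected when the baseline mean lies outside
the event CI; contiguous same-direction bins merge into bands
(single-bin gaps bridged, bands narrower than 2 bins discarded — the 2-bin
minimum is the multiplicity control that keeps the per-bin false-positive
rate of the rule a few percent on null pairs); analysis is restricted to
the 0–100 Hz acquisition band. The per-rat scalar "power increase" is
reported as the band-integrated power difference in mV² summed over
affected bands; a per-bin sum is available (`total = "per_bin_sum"`)
because the original per-rat aggregation is not uniquely defined — neither
reduction is claimed as *the* published one.

## Coherence and the surrogate null

`msc()` estimates magnitude-squared coherence with 3-s windows and 1-s
overlap ($K = \lfloor(T-3)/2\rfloor + 1$ segments). Identical channels give
1 everywhere; a single segment gives the known degenerate 1 (warned).
Independent channels give the familiar $1/K$ bias floor.

`surrogate_null()` builds the significance reference by recomputing
coherence between channel A and circularly time-shifted copies of channel
B — a deterministic sweep at multiples of the window length, excluding
shifts shorter than one window, doubled with time-reversed-B variants, and
densified to 1-s multiples when the sweep would yield fewer than 20
surrogates (a seeded sub-second jitter option exists). Circular shifts
preserve the segment count, so the null inherits the estimator's bias at
the trace's own $K$; shift and reversal surrogates are pooled.

The **confidence limit** — the value a coherence *increase* must reach to
be significant anywhere in the band — is the 95th percentile of the
surrogate distribution pooled across the 0–100 Hz bins. For broadband
traces the null is frequency-invariant, so the maximum over frequencies of
the *true* per-frequency 95th percentile coincides with this common
quantile, and pooling (~300 bins × ~50 surrogates) estimates it with
negligible error. Taking instead the empirical maximum of ~300 noisy
per-bin percentiles overstates the limit by the expected extreme of their
sampling noise (order +0.04 to +0.11 at these surrogate counts); that
literal reduction remains available as `limit_method = "max_bin"` and is
documented as conservative and surrogate-count-dependent. Against the
analytic independent-segment quantile $1-0.05^{1/(K-1)}$ — 0.221 at
$K=13$ (27-s traces) and 0.069 at $K=43$ (87-s traces) — the pooled
estimate averages 0.222 and 0.069 over 20 traces, matching the 0.22–0.061
range expected for those durations.

Per-frequency 95th percentiles are retained for per-bin testing and use
quantile type 6, whose expected exceedance by a new draw equals the
nominal level; the measured per-bin type-I error of the rule is ~5% over
200 null pairs. Significance of `coherence_change()` is one-sided by
definition — only increases at or above the limit are flagged; decreases
are reported but never "significant".

## Event and spike detection

The original delimitation was visual; `detect_ictal_events()` replaces it
with explicit rules. A 3-s sliding RMS per channel is compared against a
per-channel threshold; maximal suprathreshold runs of either channel,
at least 5 s long (the observed 5–90-s range motivates the floor) with
sub-2-s dips merged, are events. The threshold is the larger of
(a) `gain_threshold` (default 2) × baseline-epoch RMS and (b) 1.1 × the
maximum sliding RMS observed inside the baseline window. Rule (b) encodes
the study's own abnormality logic — beyond the amplitude range of normal
traces — and is what keeps high-amplitude SWS from being flagged: with a
pooled (wake+sleep) baseline RMS, rule (a) alone sits below normal sleep
excursions. A 1-s RMS window was tried first and rejected: its estimate on
delta-dominant sleep is too noisy, violating the ≥0.95 precision contract;
3 s trades a sub-second onset smear (median error ~0.5 s at gain ≥ 3)
for stability. The 1.1 margin compensates the finite baseline window
underestimating the extreme of prolonged normal activity. Postictal
suppression is reported as a descriptor (post-event RMS ratio), not used
for delimitation. Laterality is bilateral when both channels satisfy the
criterion over ≥ 50% of the event, else the qualifying channel. Activity
not lasting beyond 2 min is the working boundary between interictal runs
and ictal events; it is exposed as configuration, not asserted as a claim.

`detect_spikes()` thresholds |deviation from baseline mean| at strictly
more than `k` = 3.5 baseline SDs (boundary samples excluded — a
deterministic tie rule), groups crossings within a 100-ms refractory,
times each spike at its extremum, and averages ±250-ms peri-spike windows.
Calibration is only meaningful within a behavioral state: sleep and wake
amplitude distributions differ severalfold, so thresholding a sleep trace
against pooled statistics (or vice versa) produces spurious detections.
The pipeline therefore scans the awake segment of the final event-free
state cycle against awake-head statistics; `amplitude_ci(robust = TRUE)`
(median/MAD) is available when an epoch must serve as its own reference.

## Cohort statistics

`fisher_exact_2x2()` computes the two-sided exact p as the sum of
hypergeometric probabilities of all tables (margins fixed) no more probable
than the observed one — the probability-mass convention, which gives
p = 0.0278 for the 6/9-vs-0/6 incidence table; it is verified exhaustively
against a full-enumeration oracle for every table with N ≤ 20.
`mann_whitney()` reports U as pairwise wins plus half-ties; the default
p-value is the tie-corrected normal approximation without continuity
correction, with exact permutation enumeration for small groups. The
convention behind the originally printed rank-test p-values is unknown, so
no specific published value is asserted for them. `lesion_volume()`
implements (mean complete section area − mean damage − mean ventricle) ×
interval × section count per hemisphere; the reported lesion volume is
contralateral minus ipsilateral — a sign convention this package infers
from the volumetric method (which defines hemisphere volumes only), chosen
because it captures tissue loss including atrophy and ventricular
dilation. `peri_event_delta()` computes post-minus-pre telemetry changes
(twelve 5-min bins against the prior hour for temperature; 1-h means for
activity), excluding events preceded by another event within the pre-hour
and logging all exclusions. Group-level repeated-measures comparisons are
deliberately left to standard R modelling functions.

## Reproducibility and problem sizes

All randomness flows through explicit integer seeds; a fixed configuration
reproduces every numeric table byte for byte, and the run manifest records
parameters and seeds. The validation suite uses desk-scale sizes chosen to
make Monte-Carlo error comfortably smaller than the tolerances tested:
20 traces per coherence-limit estimate, 200 null pairs for the type-I
rate, 20 two-event recordings (~600 s each) for detection recovery, and
10 repetitions for spike-rate recovery.

## Limitations

The generator is a controllability device, not a biophysical model:
Gaussian shaped noise misses real EEG's nonstationarity within states,
asymmetric waveforms, movement/chewing artifacts, and electrode drift;
ictal morphology is a clean drifting oscillation rather than evolving
polyspike complexes; spike shape is a fixed template. Passing recovery
tests therefore demonstrates that the estimators and detectors are
correct and internally calibrated — not that their default thresholds
transfer to any particular laboratory's recordings, where artifact
rejection and state scoring would come first. The surrogate-limit
agreement is asserted against the segment-count-driven analytic
prediction, not against the original animals' traces. Detection of
unilateral events relies on per-channel thresholds, so strongly coupled
backgrounds (coupling near 1) blur laterality. EDF input is not provided;
the canonical formats are the metadata-bearing CSV and the binary
container.
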