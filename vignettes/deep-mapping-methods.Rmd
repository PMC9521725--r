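---
title: "Automated decrement-evoked-potential detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated decrement-evoked-potential detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepmapr)
```

## The measurement

Ventricular tachycardia (VT) is usually sustained by slow, decremental
conduction through surviving myocardial strands inside scar. Decrement
evoked potential (DeEP) mapping probes this substrate without inducing the
arrhythmia: the ventricle is paced with a regular drive train (S1, here a
600 ms cycle length) followed by one premature extra-stimulus (S2)
delivered near the effective refractory period. On each bipolar electrode
the near-field evoked potential (EP) trails its stimulus by a latency; in
healthy tissue that latency is essentially rate-independent, whereas
decremental tissue responds to the premature beat with extra delay. The
decrement is

$$\mathrm{DeEP} = t_{EP}(S2) - t_{EP}(S1_{\mathrm{last}})\quad[\mathrm{ms}],$$

the S2 EP latency minus the latency of the last drive-train EP, computed
independently per bipolar electrode. Decrements above roughly 10 ms mark
arrhythmogenic substrate and are displayed as size-scaled spheres on the
3D voltage map of the chamber.

`deepmapr` implements the full automatic workflow: pacing-artifact
detection, S1/S2 train classification, capture confirmation on the surface
ECG, S1 EP detection with a stability check on the last 3 drive beats, S2
EP detection by template matching, decrement computation, the display
threshold, 3D mapping, and the validation statistics used to score the
algorithm against expert annotations.

## Pipeline stages and their assumptions

### Pacing-artifact detection

The stimulus artifact is broadband, impulse-like and appears on
essentially every channel at once. A sample is a candidate when its
absolute amplitude exceeds `stimulus.threshold_mv` (2 mV; artifacts are
several mV while electrograms are fractions of a mV); per-channel
candidate runs are merged within the 50 ms refractory period and
represented by their absolute peak; peaks coincident across at least
`stimulus.coincidence_fraction` (50%) of all channels within 2 ms become
one stimulus event. A final refractory pass guarantees a 50 ms dead time
between events. The assumptions are that the pacing channel is routed into
the recording (so the artifact is visible everywhere) and that no
physiological deflection reaches artifact amplitude simultaneously on half
the channels.

### Train classification

The drive cycle length is estimated as the median inter-event interval
after iteratively discarding intervals shorter than half the running
median — robust to the single short S2 interval. Events whose preceding
interval is within the jitter band (`stimulus.jitter_fraction`, 5%) of the
cycle length are S1. The first event whose preceding interval is at least
`stimulus.s2_shortening` (10%) shorter than the cycle length *is* the
extra-stimulus and ends the train; an interval at least 10% shorter is the
defining property of a premature stimulus here, and a train in which no
interval qualifies carries no S2, in which case no decrement can be
defined and the pipeline terminates for that train with a typed, logged
`no_s2` disposition. Only one extra-stimulus per train is recognized;
multi-level protocols (S3/S4) are out of scope.

### Capture confirmation

A decrement is only interpretable if the stimuli actually captured the
ventricle. Capture shows as a reproducible paced QRS, so each beat's
surface-lead segment (20–140 ms post-stimulus, covering the paced QRS) is
correlated at zero lag against a template formed as the per-lead
sample-wise *median* of all S1 segments — the median so that one
non-captured beat cannot drag the template. The per-beat score is the
Pearson correlation averaged over leads; a beat is captured when the score
reaches `capture.threshold` (0.90). Because Pearson correlation is
amplitude-invariant, rescaling the surface gain changes no decision. The
measurement beats — the last 3 S1 and the S2 — must all be captured,
otherwise the train terminates `capture_indeterminate`. Which leads enter
the average is configurable (`capture.leads`, default all).

### Near-field EP detection

Bipolar electrograms superimpose the local near-field response on the
smooth far-field ventricular complex. Separation is by zero-phase
Butterworth band-pass filtering (`ep.band_hz`, 30–300 Hz: the far-field
paced QRS concentrates below ~30 Hz, the near-field EP carries its energy
well inside the band) plus window gating. Before filtering, samples within
±3 ms of each stimulus are blanked by linear interpolation: a
multi-millivolt artifact would otherwise ring through the filter into the
search window and mask sub-millivolt EPs.

For each of the last 3 *captured* S1 beats the EP fiducial is the time of
maximum absolute filtered amplitude in the window from 10 ms
post-stimulus to 90% of the gap to the next stimulus (the drive cycle
length, or the shorter S2 coupling for the final drive beat), provided it
exceeds the noise floor, `ep.noise_mult` (3) times the channel's robust
MAD-based standard deviation. The peak was chosen as the fiducial — rather
than onset or steepest slope — because it is the most noise-robust
landmark and the decrement is a *difference* of two latencies measured
with the same convention, so the choice cancels. "Last 3 captured beats"
generalizes the 8-beat clinical protocol to any train of at least 3
captured drive beats without changing behaviour on 8-beat trains.

Stability of the drive-train response is required before the premature
response can be attributed to decrement: the population standard deviation
of the 3 latencies must not exceed `ep.stability_sd_ms` (5 ms) and the
mean pairwise normalized correlation of the ±10 ms morphology windows must
reach `ep.stability_corr` (0.85). Both cutoffs are package defaults, not
literature constants. An unstable channel is skipped (logged); the rest of
the train proceeds — instability is a local property of one bipole.

### S2 EP detection

The last stable S1 morphology window is the template. It is slid over the
band-limited post-S2 window (10 ms after S2 to the end of the recording)
and the lag is chosen by matched filtering — the placement maximizing the
inner product of template and signal. The matched filter is the optimal
detector for a known waveform in additive noise and weights shape
agreement by amplitude, which matters in practice: band-limited noise is
locally oscillatory and can *correlate* well with an oscillatory template
at negligible amplitude, so a pure correlation maximum occasionally locks
onto noise. The chosen placement is accepted only if it contains a
deflection above the same 3×MAD noise floor used for S1 detection and its
normalized correlation with the template reaches `ep.s2_match_threshold`
(0.7); otherwise the EP is reported absent — a premature stimulus at the
refractory limit may genuinely block, and absence must be distinguishable
from a zero decrement.

### Decrement, threshold, mapping

The decrement is the plain latency difference; negative values (S2
response found *earlier* than the drive response) are physiologically
implausible, indicate an upstream detection fault, and are retained with a
`negative` flag rather than clipped — silent clipping would hide pipeline
faults from quality control. The display threshold is strict
(`deep_ms > threshold`, default 10 ms): a point exactly at threshold is
hidden.

For mapping, each electrode's bipolar voltage is the peak-to-peak
amplitude in a 200 ms window after the last captured S1 stimulus; vertex
values are inverse-distance-weighted (power 2) averages of electrodes
within `map.radius_mm` (10 mm), with uncovered vertices marked no-data.
Displayed points are projected to their nearest mesh vertex (points
farther than `map.projection_limit_mm`, 15 mm, are excluded with a
warning) and drawn as spheres of radius
`r_min + k · DeEP` (1 mm + 0.05 mm/ms), a linear law chosen for strict
monotonicity; the true clinical scaling law is unknown. The conventional
0.5/1.5 mV scar/border voltage colour thresholds travel as export
metadata only.

## The synthetic generator

No public paced-recording corpus with per-electrode decrement ground truth
exists, so `simulate_recording()` manufactures one and is itself
first-class, tested code. It emulates the structure the detection stages
rely on: an 8-beat S1 train at 600 ms cycle length plus one S2 at a 300 ms
coupling interval (a typical ventricular effective refractory period at
this rate), a 2 ms biphasic 5 mV pacing artifact on every channel, a
common smooth ~100 ms paced-QRS template (1 mV on the surface, 0.2 mV
far-field on bipoles), and on each bipolar channel a 15 ms, 150 Hz Gabor
wavelet of 0.5 mV as the near-field EP — at 40 ms base latency after S1
and at base latency plus the planted decrement after S2. The wavelet is
symmetric with its absolute maximum exactly at its centre sample, so the
planted fiducial is unambiguous and survives zero-phase filtering.
Capture-failure beats keep the artifact but omit QRS, far-field and EP;
blocked channels omit the S2 EP entirely. White Gaussian noise of
configurable standard deviation is added per channel; one global seed
drives all randomness, so identical configurations are bit-identical.

What the generator does *not* emulate — and what passing tests therefore
do not establish about clinical data: fractionated multi-component EPs,
fusion and pseudo-fusion beats, baseline wander and mains interference,
catheter motion, beat-to-beat far-field variation, and rate-dependent
(restitution) latency drift within the drive train. The validation here
shows the algorithm is correct *given* the paced-recording structure; the
published multicenter statistics quantify behaviour on real signals.

## Numerical conventions and degenerate inputs

Times are milliseconds from recording start (floating point), sample
indices are 0-based on disk and 1-based in R, windows are half-open
`[start, end)`. Sampling rates below 1000 Hz are rejected: latencies are
reported at sample resolution, and millisecond-scale decrements need
sub-millisecond resolution. Correlation of a numerically constant segment
is defined as 0 (a flat window carries no morphology evidence).
Sensitivity, specificity and Cohen's kappa with empty denominators
(`tp + fn = 0`, `tn + fp = 0`, chance agreement 1) return a typed
`undefined` value, never 0 or 100. Population (divide-by-n) standard
deviation is used for the 3-beat stability statistic. All early
terminations (`no_s2`, `capture_indeterminate`, `insufficient_s1`,
`unstable_s1`, `s2_ep_absent`) are values carried through the pipeline and
logged — one JSON line per decision — never exceptions.

Interchange formats: the JSON+CSV recording dialect writes samples with 17
significant digits and round-trips doubles bit-exactly; the WFDB dialect
(format 16) is exact at the declared ADC gain (default 1000 units/mV, i.e.
1 µV), which is the resolution clinical amplifiers provide. Mesh exports
(legacy ASCII VTK, ASCII PLY) round-trip scalars to at least 6 significant
digits.

## Validation statistics

Algorithm output is scored against a gold standard per *unit* — one
potential DeEP site, i.e. one channel of one train: TP/TN/FP/FN by joint
marking, sensitivity `100·TP/(TP+FN)`, specificity `100·TN/(TN+FP)`,
Cohen's kappa from the 2×2 marginals, and the four-way correction taxonomy
(unchanged / changed / deleted / added) with a 5 ms decrement-difference
tolerance separating "unchanged" from "changed" (the clinical criterion is
not numeric; 5 ms is a package default). Percentages are reported to one
decimal.

## Problem sizes used in the shipped checks

The test-suite and acceptance computations use an 8+1-beat train at
1000 Hz sampling, recordings of roughly 5 s, up to 200 bipolar channels
with decrements drawn uniformly on [0, 80] ms, and a noise standard
deviation of 0.05 mV — one tenth of the EP amplitude. At these sizes the
clean-limit run recovers every planted decrement exactly at sample
resolution and the noisy run recovers them with a mean absolute error an
order of magnitude below the 10 ms clinical display threshold.

## Known limitations

* One extra-stimulus per train; S3/S4 protocols are not classified.
* Near-field/far-field separation is purely spectral + temporal; a
  far-field component inside 30–300 Hz overlapping the search window
  would be indistinguishable from a near-field EP.
* The EP fiducial is the filtered-peak convention; absolute latencies are
  convention-dependent even though decrements largely cancel the choice.
* The voltage map uses a single paced beat and inverse-distance weighting;
  it is a display aid, not a validated scar delineation.
* Stability failure skips only the affected channel; whether clinical
  software discards the whole train in that case is unknown.
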