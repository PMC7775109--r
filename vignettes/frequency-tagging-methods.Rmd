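---
title: "Frequency-tagged analysis of syllable and word rhythms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagged analysis of syllable and word rhythms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmtag)
```

## The experimental logic

In a frequency-tagging speech experiment, syllables are presented at a fixed
rate (here 4 Hz) so that any neural activity locked to syllable onsets is
confined to discrete spectral lines at 4 Hz and its harmonics. If the
narrative is *metrical* — constructed so that every odd-position syllable
within a sentence (sigma1) begins a word — then word onsets recur at half the
syllable rate, and activity locked to word onsets appears at 2 Hz. A
*nonmetrical* narrative, in which word onsets are not aligned with the
sigma1/sigma2 parity grid, provides the control: its word-onset train carries
no 2-Hz line, so a 2-Hz response peak indexes the brain's tracking of the
word rhythm rather than any acoustic periodicity.

Amplitude modulation (AM) adds an acoustic 2-Hz cue: either all sigma1 or
all sigma2 syllables are amplified fourfold. Because every sigma2 syllable
follows its sigma1 neighbour by exactly 0.25 s, the sigma2-amplified
stimulus is the sigma1-amplified stimulus delayed by 0.25 s — a 180-degree
phase shift at 2 Hz. Word onsets, by contrast, are identical in both
conditions. This asymmetry is the key design device:

* a response locked to **word onsets** has a 0-degree 2-Hz phase difference
  between the two AM conditions;
* a response locked to the **amplified syllables** has a 180-degree
  difference;
* averaging the two condition responses cancels the AM-locked 2-Hz
  component (the *word response*); averaging after delaying the
  sigma1-condition response by 0.25 s cancels the word-locked component
  (the *AM response*).

The package implements this full chain — stimulus construction, forward EEG
simulation, preprocessing, spectral and circular statistics, time-warping
for natural timing, component separation, and the inferential layer — so
that every stage can be validated end to end on synthetic data with known
ground truth.

## Stimulus model

`generateMetricalTimeline()` tiles sentences from two-syllable "feet": each
foot is a disyllabic word with probability `pDisyllabic`, otherwise a pair
of monosyllabic words. Both satisfy the metrical constraint (sigma1 is
always a word onset). The published material reports both 77% and 73% for
the fraction of sigma2 syllables that are second syllables of disyllabic
words; we default to 0.77 and keep both values reachable through
`pDisyllabic`. Note a consequence tested in the suite: with the 0.77 mix the
word-onset train includes irregular sigma2 positions (monosyllabic words),
so only the sigma1 sub-train is exactly 2-Hz periodic; the 2-Hz line still
dominates, but the strict "power only at 2-Hz harmonics" identity holds
only for an all-disyllabic text.

Sentence lengths are drawn uniformly from the even counts 8–20 syllables, a
choice we fixed once to match narrative-like sentence spans at 4 syllables/s
(2–5 s per sentence); only word counts per story are reported for the
original material. A 0.5-s silence (two syllable periods) follows every
sentence, standing in for punctuation pauses.

Isochronous timing sets every syllable to 0.250 s. Natural timing draws
durations from a log-normal distribution truncated to [0.075, 0.354] s with
its location parameter solved so the truncated mean is exactly 0.224 s —
the published range and mean of the synthesised syllable inventory; the
shape parameter (sdlog 0.25) was fixed once as a plausible spread given only
those two constraints. `renderEnvelope()` renders the amplitude envelope
only (unit syllables, fourfold amplification, 25-ms raised-cosine offset
taper, silent gaps); no carrier fine structure is modelled.

A deliberate arithmetic property of the design is preserved throughout: all
excisable spans — the 0.5-s punctuation gap and the 0.5-s two-syllable
sentence prefix — are integer multiples of the 0.5-s word period, so
excision and concatenation never break the 2-Hz or 4-Hz phase. The test
suite asserts this with a probe sinusoid.

## Forward EEG simulator

`simulateRecording()` implements a linear additive model: each component
(word-locked, syllable-locked, AM-locked) is an impulse train at its event
onsets convolved with an evoked-response kernel supported on [0, 0.75] s,
scaled in microvolts, and spread across channels by a topographic weight
map (centro-frontal for the word and syllable components, temporal for the
AM component, echoing the distinct topographies of the word and AM
responses). Background noise is 1/f^alpha Gaussian (alpha = 1 by default),
independent across channels; ocular activity is a random walk injected into
VEOG/HEOG and leaked into frontal channels by per-channel gains; occasional
large transients (hundreds of microvolts, ~0.15 s) can be injected at a
configurable rate to exercise masking and trial rejection. With the default
rate used by the pipeline presets (0.015 events/s, about one contaminated
trial in ten) the automated rejection fraction falls in the 5–20% band
reported for visual inspection.

What the simulator emulates: the event-locking structure, the 0.25-s
translate relation between AM conditions, component topographies,
1/f background, ocular leakage amenable to regression, and between-subject
amplitude (log-normal) and latency (Gaussian) variability. What it does not
emulate: volume conduction from realistic sources, correlated noise across
channels, non-stationary artifacts (movement, electrode drift-jumps), or
any nonlinearity in the response. Passing tests therefore demonstrate the
*analysis machinery* — not that real cortical data behave this way.

Kernels (`makeErpKernel()`) are gamma lobes (single-sign, peak at a given
latency) or Hann-windowed sine cycles (biphasic, zero-mean). Two numerical
consequences matter and are exploited by the validation suite:

* **Compact AM kernels.** When the AM kernel's support fits inside one
  0.25-s half-cycle, the AM-locked response is exactly periodic at the word
  rate within sentences, and the 180-degree identity and the
  phase-cancellation identities hold to machine precision. The default AM
  kernel (gamma, latency 0.12 s, width 0.12 s) satisfies this.
* **DC pedestal of single-sign kernels.** An all-positive kernel train
  carries a sentence-length DC pedestal. The 0.8-Hz high-pass removes it by
  design, which perturbs the 2-Hz trial bin by a few percent after
  splicing. Amplitude-preservation checks therefore use zero-mean kernels;
  with real (zero-mean, high-passed) EEG this interaction does not arise.

## Preprocessing chain

The stages run in a fixed order — downsample (to 128 Hz), mastoid
re-reference, band-pass filter, EOG regression, artifact masking — followed
by sentence-aware segmentation and trial rejection; the order is recorded
in each object's provenance and asserted by a test.

The band-pass filter is a linear-phase Hamming-windowed-sinc FIR, 0.8–30 Hz,
with `6 * fs + 1` symmetric taps (a 6-s design window; the odd tap count
makes the N/2-sample group delay an integer). The windowed-sinc construction
crosses each cut-off at exactly −6 dB (gain 0.5). Delay is compensated by
dropping the first N/2 output samples; the trailing N/2 samples are dropped
too, so every retained sample is fully filtered. We construct the taps
directly because the property tested — −6 dB at the cut-offs — is a defining
feature of this design.

Noise-free *design checks* (the phase identities, peak-bin checks) skip the
band-pass stage: with no noise there is nothing to remove, and the 6-s
filter's sentence-boundary transients bias the AM phase difference by about
a degree, obscuring identities that are otherwise exact to 1e-13. All noisy
analyses keep the filter.

EOG regression removes the ocular component by least squares on HEOG and
VEOG (plus intercept), leaving residuals orthogonal to both. Because the
1/f background shares its lowest-frequency band with the ocular random
walk, gain recovery has an identifiability floor set by the
ocular-to-background ratio; the 1%-recovery contract is evaluated where the
ocular component dominates, as it does in practice for frontal channels.

Samples exceeding 1 mV are masked, never altered; a 7-s trial containing
any masked sample is rejected rather than interpolated (conservative — the
interaction of masked samples with the trial grid is not specified in the
source method). Automated rejection replaces visual inspection with two
logged criteria: peak-to-peak above 200 uV on any channel, or mean channel
variance above four times the median across trials.

Segmentation keeps, per sentence, the span from the third syllable's onset
to the last syllable's offset (removing sound-onset responses and gaps),
concatenates the spans, and cuts consecutive 7-s trials; a tail shorter
than one trial is discarded. Event-to-sample mapping is nearest-sample
rounding with 0-based indexing and half-open intervals.

## Spectral conventions

`averageAndSpectrum()` averages trials coherently in the time domain and
then applies a DFT per channel with no taper, so the bin spacing is 1/7 Hz
and 2 Hz falls on bin 14. Coefficients are divided by the sample count:
a unit cosine appears with magnitude 1/2 and its cosine phase (time zero =
trial start); power is the squared magnitude with no one-sided doubling.
Absolute normalisation cancels in every comparison the pipeline makes; a
Parseval audit test pins the convention. The peak statistic is power at the
target bin minus the mean of the two bins on each side, per channel and
channel-averaged; off-grid target frequencies are an error rather than a
silent nearest-bin match. Phases are always combined with the circular mean
(the direction of the mean resultant vector), never arithmetically; a
resultant length below 1e-12 flags the mean as undefined (antipodal
degeneracy). Power grand averages are taken over channels, then
participants; condition phase differences are averaged over participants
per channel (circular mean), then over channels.

## Time-warping

For natural timing, the response to each syllable (0–750 ms from onset) is
extracted and the warped response is the overlap-add of these segments on
the 0.25-s grid — the convolution of the segment set with a 4-Hz impulse
train. No windowing or crossfading is applied, matching the plain
convolution. Design choices: segments whose window runs past the recording
end keep their grid slot zero-filled (renumbering would corrupt the 2-Hz
phase bookkeeping); sentence gaps remain as silent slots and are excised by
the same segmentation as the isochronous pipeline. Two properties bound the
interpretation: when each segment is exactly the per-syllable kernel, the
warp reproduces the isochronous simulation sample for sample; when
segments are sliced from a recording whose responses overlap in time,
overlapping content is summed repeatedly (roughly tripling interior
amplitude for 0.75-s windows at a 4-Hz rate), which rescales the spectrum
but leaves peak positions and phases intact — the quantities the analysis
uses.

## Component separation

`wordAverage()` and `amAverage()` operate on trial-averaged waveforms. The
250-ms realignment delay is applied as a circular shift within the 7-s
trial: trials are phase-continuous concatenations whose excised spans are
multiples of the 0.5-s word period, so the wrap preserves exact 2-Hz
antiphase cancellation (a truncation-based shift would not). A delay that
is not an integer number of samples at the analysis rate (32 samples at
128 Hz) is rejected rather than interpolated. Topographies are normalised
by their maximum for shape comparisons. ERP analysis is restricted to
disyllabic words: per-word epochs over [−0.1, 0.75] s, baseline-corrected
on the 100-ms pre-onset window, averaged separately over first (sigma1) and
second (sigma2) syllables.

## Statistics

All resampling tests are deterministic given their seed and respect the
p-value floor `1/(n + 1)`.

* **BCa bootstrap** (`bootstrapEngine()`): participants are resampled with
  replacement (default 10,000 times); the bias term comes from the fraction
  of resampled statistics below the point estimate and the acceleration
  from a leave-one-out jackknife. The implementation agrees with the
  `boot` package's BCa intervals to numerical identity on shared resamples.
  At n = 16 the method itself covers ~92–93% at a nominal 95% — the known
  small-sample behaviour, not an implementation artifact.
* **Peak significance** (`spectralPeakTest()`): the published rule
  "p = (N + 1)/10,001" is ambiguous about what N counts; as literally
  written, more favourable resamples would *raise* p. We take N as the
  number of resamples that contradict the alternative (peak not above its
  neighbours), so the strongest evidence yields the floor 1/10,001 —
  consistent with the reported floor p = 0.0001. Two-sided condition
  comparisons use `(2N + 1)/10,001` with N the minority tail count, making
  the test symmetric under condition swap.
* **Cross-experiment comparison** (`crossExperimentTest()`): the source
  formulation compares one experiment's observed mean against the
  percentile of the *other* experiment's bootstrapped-mean distribution.
  Taken literally this ignores the first group's sampling variability and
  inflates the type-I error to ~0.15 at n = 16. We evaluate the percentile
  of zero in the bootstrap distribution of the between-group mean
  difference, which reduces to the literal rule when one group's
  variability vanishes and holds the nominal level (~0.06 measured).
* **Phase inference**: circular confidence intervals are the shortest arc
  covering V% of the resampled circular means; the phase-coherence test
  compares the observed mean resultant length against coherences of
  uniformly drawn phase sets.
* **Cluster-based permutation test**: pointwise paired t statistics,
  two-sided pointwise alpha 0.05 forming clusters (the cluster-forming
  threshold is not specified in the source; it is configurable), same-sign
  temporal adjacency, cluster statistic = sum of t values, and a null of
  within-participant condition exchange (sign flips) summarised by the
  maximum |cluster statistic|; ties count against rejection. Clustering is
  over time only — no channel adjacency.
* **FDR**: Benjamini–Hochberg step-up via `stats::p.adjust`. Which
  comparisons form a family is not enumerated in the source; the pipeline
  treats each run's panel of peak tests as one family.
* **Effect size**: Cohen's d for paired differences with achieved power
  from the noncentral t (`stats::power.t.test`), replacing external
  power software.

## Problem sizes and runtime choices

The validation suite runs the parameter-recovery study at the full scale of
the design — 148 seven-second trials per condition and 16 virtual
participants — with four scalp channels, which is sufficient because
recovery accuracy is a per-channel property. Null-calibration studies use
250–600 replicates with 1,000 bootstrap resamples or 500 permutations;
binomial error on a 5% rejection rate is then under one percentage point.
Design-identity checks use ~40-sentence narratives (240 syllables), where
every identity is already exact. The single-trial 2-Hz signal-to-noise
ratio for the recovery study is calibrated to −10 dB by measuring the
simulator's own signal and unit-noise bin powers, so the noise level is
derived, not tuned.

## Known limitations

* The simulator's noise is spatially white; real EEG noise is spatially
  correlated, which mainly affects how much channel averaging helps.
* Trial rejection is an automated proxy with fixed thresholds; it
  reproduces plausible rejection rates but not the judgement of a human
  rater.
* The EDF writer targets the plain (continuous, uniform-rate) profile —
  sufficient for data exchange, not a general EDF+ implementation.
* Cluster inference controls family-wise error over time within one
  comparison; it does not address selection across electrodes.
* The phase-design identities are exact only under the conventions stated
  above (compact AM kernels, wrap-around realignment, filter-free
  noise-free checks); they degrade gracefully — by about a degree — under
  the full noisy chain.
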