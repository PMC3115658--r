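---
title: "Multichannel crackle analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multichannel crackle analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cracklelab)
```

## The problem

Crackles — short, explosive, discontinuous sounds superimposed on breath
sounds — are a hallmark of interstitial pulmonary fibrosis (IPF), but at
the bedside they are easily confused with the crackles of congestive
heart failure (CHF) and pneumonia (PN), and the confusion has real
therapeutic consequences. Recorded over the posterior chest with a
multichannel microphone array, however, the three diseases produce
measurably different crackles: IPF crackles are numerous, short and
high-pitched, scattered over both lungs, and transmit poorly to
neighbouring microphones; CHF crackles are slower, accentuated toward
the lung bases, and transmit widely; PN crackles cluster in one focal
region with intermediate transmission.

`cracklelab` implements the full measurement-and-classification chain
for such recordings — and, because no public multichannel crackle corpus
exists, a seeded synthetic-recording generator with per-disease profiles
so that every stage can be exercised and validated against known ground
truth.

## The crackle waveform model

A crackle is modelled as a train of `n` half-sine lobes of alternating
sign. Lobe `i` has duration `T_i` (ms) and amplitude `A_i`; the first
lobe contains the highest peak, whose direction defines the crackle's
polarity. Durations follow `T_1` and `T_i = r * T_1` for `i > 1`, where
`r` is the T2/T1 ratio; amplitudes decay geometrically. The crackle
pitch is defined from the first four half-periods,

    pitch [Hz] = 2000 / (T1 + T2 + T3 + T4)   (T in ms),

and is computed from measured half-period durations, not from a spectral
transform: the half-period decomposition is the primary measurement, and
keeping pitch a deterministic function of it makes generation and
measurement exactly inverse to one another on clean waveforms (the
parameter-recovery tests assert equality within one sample period).

The number of baseline crossings (ZXS) is reported as `n + 1`: the
crossings bounding the retained half-periods, including the onset and
final crossing. One convention had to be fixed — the field's definition
("times the waveform crosses the baseline") does not say whether the
bounding crossings count — and this one reproduces the published
relationship between ZXS and crackle length.

T1 units deserve a note. The group tables in the clinical literature
print T1 near 1.2 with unit "(s)", which is physically impossible next
to a 416 Hz pitch; with T1 read as milliseconds, 2/(4 × 1.2 ms) = 416.7
Hz exactly matches. T1 is milliseconds everywhere in this package.

The three built-in profiles cannot take pitch, T1 *and* r from the
published group means simultaneously (the triplet is over-determined and
inconsistent); the generator treats pitch and r as generative and
derives T1, which preserves the published group ordering of T1
(IPF < CHF < PN).

## The synthetic-recording generator

`synthesize_recording()` draws, for one patient:

* **Breaths.** `n_breaths` equal breaths over `duration` seconds
  (defaults 3 and 20 s — one deep-breathing recording), inspiration
  occupying 40% of each breath. Boundaries are carried as ground truth.
* **Crackle counts** per breath and phase from the profile's rate
  distributions, truncated at zero.
* **Waveform parameters** per crackle. Published per-group standard
  deviations describe variation *across patients*, so each profile SD is
  split into a patient-level and a crackle-level component of equal
  variance (a 50/50 split; the group-comparison stage then sees
  realistic between-patient spread rather than the vanishing SD that a
  purely crackle-level draw would give). Within a crackle, half-period
  durations and amplitudes get mild log-normal jitter (sigma 0.18 and
  0.15). Heavier duration jitter produces lobe patterns whose baseline
  crossings vanish after band-pass filtering — real measurement physics,
  but it costs ~20% of crackles to the four-half-period validity rule,
  so the default stays mild; the price is that measured within-crackle
  duration variability (~20–25%) undershoots the published ~37–43%.
* **Source locations** per the profile's spatial pattern: `uniform` over
  the lung volume; `basal` with linear density doubling toward the
  lowest third; `focal` with all sources in one seeded quadrant.
* **Transmission.** Each crackle is projected onto every ipsilateral
  microphone with arrival delay distance/sound-speed (3 cm/ms by
  default) and child amplitude `A_mother * g * exp(-d/lambda)`
  (`lambda` = 15 cm). The gain `g` is solved per crackle so that the
  transmission coefficient the *measurement stage is expected to
  report* equals the profile's transmission level: children whose
  amplitude would fall below the detection floor count zero, and are
  not inserted into the signal at all — an unmeasurable child would
  only blur the calibration. The floor tracks the breath-sound envelope
  because the detector's background rises during loud inspiration; its
  scale (3.5 × noise RMS) was calibrated once against the full
  measurement chain so that cohort-mean measured CTC lands within about
  one point of the nominal level for all three profiles.
* **Background.** White Gaussian noise (RMS 0.05 in the signal's
  arbitrary units, i.e. ~20 dB below the median crackle peak of 0.5)
  plus a band-limited (<300 Hz) breath-sound component, amplitude-
  modulated per phase (inspiration louder), one realization per side of
  the chest.

Everything is drawn from a single seeded stream: identical arguments
give bit-identical signals and annotations.

What the generator does *not* emulate: heart sounds, wheezes, airway
transmission filtering (children are scaled copies of the mother
waveform), anterior-chest acoustics, variable breath lengths, sensor
artefacts. Passing tests on these recordings therefore demonstrate the
*internal* consistency of the chain — detection, decomposition,
grouping, transmission, voting — not clinical performance on real
patients.

## Detection and segmentation

The detector band-passes each channel (order-4 Butterworth, 100–2000
Hz; all filtering is zero-phase, applied as the squared magnitude
response in the frequency domain), scores every sample as rectified
amplitude over a 200 ms trailing background RMS (computed on an
amplitude-clipped copy so crackles do not inflate their own
background), and requires score > 4. Two structural criteria remove
what a threshold alone cannot: a candidate must rise explosively (the
signal must be below 10% of the peak within the 3 ms preceding it) and
must carry sustained transient energy (3 ms local RMS at least twice
the background) — isolated noise exceedances essentially never satisfy
the latter, which is what makes a 20-second, 16-channel recording of
pure noise yield zero detections. Supra-threshold runs closer than the
10 ms dead time merge; each event is windowed 20 ms around its highest
deflection. Feature windows are cut from an order-2 filter over the
same band: the steeper detection filter's baseline sag can swallow the
zero crossings of a short weak half-period squeezed between two large
opposite lobes.

Breath segmentation uses the true boundaries when the recording carries
them (all synthetic work does). The estimation path — for recordings
without annotations — smooths the <300 Hz envelope, takes tall humps as
inspirations, and ends each breath just before the next inspiratory
hump; it recovers breath counts and inspiratory boundaries to a few
hundred milliseconds on synthetic recordings, and is deliberately
simple.

## Half-period decomposition conventions

`decompose_half_periods()` subtracts the window median (a robust
baseline that is exactly zero on clean padded waveforms), finds
baseline crossings with linear interpolation (sub-sample accuracy),
takes T1 as the half-period containing the highest |peak|, and
enumerates rightward until a half-period's amplitude falls below the
floor — 10% of the peak, but never below 1.5× the window's pre-onset
noise level. Noise briefly re-crossing the baseline inside a genuine
half-period splits off slivers far shorter than any physiological
half-period (< 0.4 ms); these are merged back into their neighbours.
Crackles retaining fewer than four half-periods are discarded with a
reason and counted in the diagnostics — the same attrition a hardware
crackle counter applies.

## Families, transmission and localization

Per-channel events are grouped greedily: the largest unassigned event
becomes a mother crackle and collects all unassigned ipsilateral events
within ±10 ms, one per channel (nearest in time). With `N` channels on
the mother's side, the crackle transmission coefficient is

    CTC [%] = 100 / (N - 1) * sum over other ipsilateral channels of
              min(A_child / A_mother, 1),

absent channels contributing zero. This is the simplest form satisfying
the defining endpoints — 0% with no transmission, 100% with equal
transmission everywhere — and monotonicity in child amplitude; the
original instrument's exact formula is not public, so this is an
explicit, documented approximation, and the generator calibrates
against this same formula. Mother selection is by amplitude; the
earlier arrival of the mother is a diagnostic, not a selection key.

Families with at least three members are localized by least squares on
arrival-time differences (delays predicted as distance/sound-speed
relative to the mother; L-BFGS-B inside the chest bounding box, started
at the mother's position projected 6 cm into the chest). Smaller
families fall back to that projected position. With exact delays the
multilateration recovers sources to under 1 cm; with sampled, noisy
peaks errors are a few cm, which is adequate for the per-breath
distance aggregates.

## Aggregate features and classification

Per breath: the crackle count, counts per chest quadrant (quadrant of
the mother channel, so single-channel families still contribute), the
six pairwise quadrant percentage differences
`100 * (n_i - n_j) / max(n_i + n_j, 1)` in the fixed order (TL,TR),
(TL,BL), (TL,BR), (TR,BL), (TR,BR), (BL,BR), and maximum distances
between crackles (per axis and Euclidean), both for localized sources
and for mother-microphone positions.

Classification is hierarchical. A crackle-level binary classifier — an
RBF-kernel SVM or a single-hidden-layer (16-unit) backpropagation
network, both on features standardized by training statistics only —
labels individual crackles. Breaths are labelled by majority vote over
their crackles, or, in the aggregate mode, by a second-stage classifier
fed the breath's vote fractions and mean scores concatenated with its
aggregate feature vector. Patients are labelled by majority vote over
breaths; ties break by summed score, then class priority. Evaluation is
five-fold cross-validation with folds split at the *patient* level,
stratified by class — crackles of one patient are strongly correlated,
and splitting them across folds would inflate every metric. Breaths
with no detected crackles are excluded from voting and counted.
Sensitivity/specificity/accuracy are reported with IPF as the positive
class at every level.

On study-scale synthetic cohorts (39 IPF / 95 CHF / 123 PN patients,
one 20 s recording each) the group comparison flags pitch, T1, ZXS and
CTC at p < .05 for both tasks and patient-level cross-validated
accuracy exceeds 0.9 — comfortably above the 0.8 the qualitative
reproduction demands. Synthetic cohorts are *easier* than real ones
(the generator draws groups from cleanly separated distributions), so
these numbers mirror the direction of the published results, not their
values.

## Statistical reporting

`compare_groups()` reports per-patient means (the default summary;
medians are also computed) per feature and phase as mean ± SD per
group with two-sample t-tests of IPF against each other group. Welch's
unequal-variance form is the default — the published group SDs differ
visibly — with the pooled classic form behind `var_equal = TRUE`. No
multiple-testing correction is applied, matching the raw per-row
p-values of the source tables; same-profile null cohorts flag ~5% of
rows, as the type-I calibration test asserts.

## Problem sizes and determinism

The test-suite defaults were chosen to keep a full run on one CPU in
the tens of minutes: the study-scale cohort (257 patients, 14 posterior
channels, 20 s at 8 kHz) is built once and shared between the tests
that need it; calibration tests use 6–70 patients. All stochastic
stages take explicit integer seeds, and every result in this vignette
and the README is recomputed by the tests or the analysis scripts —
none is asserted from memory.

## Known limitations

* The CTC formula is a documented stand-in for the instrument's
  unpublished one; only its endpoints and monotonicity are anchored.
* Detection attrition is biased toward small-amplitude, low-pitch
  crackles (their fourth half-period is the first to drown); measured
  ZXS therefore undershoots the generated half-period count for long
  IPF crackles truncated by the 20 ms window.
* The breath segmenter assumes the generator's loud-inspiration
  envelope shape.
* Synthetic-cohort classification accuracies should be read as an
  upper bound sanity check of the pipeline, never as clinical
  performance.
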