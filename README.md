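# cracklelab

Multichannel lung-sound crackle analysis in R: simulate disease-profiled
chest-surface recordings, detect and decompose crackles, measure how
strongly each crackle transmits across the chest, and classify patients
by hierarchical majority voting.

## The problem

Crackles — short explosive adventitious lung sounds — are often the
first clue to interstitial pulmonary fibrosis (IPF), but at the bedside
they are easily mistaken for the crackles of congestive heart failure
(CHF) or pneumonia (PN), and patients then receive diuretics or
antibiotics they do not need. Recorded with a multichannel microphone
array over the posterior chest, however, the three diseases differ
measurably: in how many crackles occur per breath, in the crackle
waveform itself, in where the crackles sit in the lung, and in how far
each crackling event transmits to neighbouring microphones.

`cracklelab` is for signal-processing and biomedical researchers who
want a complete, testable implementation of that measurement chain. No
public multichannel crackle corpus exists, so the package includes a
seeded generator whose three built-in disease profiles reproduce the
published per-group crackle statistics; every downstream stage is
validated against the generator's ground truth.

## The measurements

A crackle window is decomposed into **half-periods** — intervals
between baseline crossings — with `T1` the half-period containing the
highest peak. From the decomposition come the individual crackle
features: the crackle pitch

    pitch [Hz] = 2000 / (T1 + T2 + T3 + T4)     (durations in ms),

the zero-crossing count ZXS, T2/T1, duration and amplitude
variabilities (SD/mean × 100%), amplitude ratios A2/A1 and A3/A1,
polarity (direction of the highest peak), and a 1–6 timing code (early/
mid/late thirds of inspiration and expiration).

Simultaneous detections across same-side microphones are grouped into a
**crackle family** around the loudest member (the *mother crackle*).
With `N` ipsilateral channels, the **crackle transmission coefficient**

    CTC [%] = 100/(N-1) * sum_c min(A_c / A_mother, 1)

is 0% when nothing transmits and 100% when every ipsilateral channel
receives the mother's amplitude. Arrival-time differences localize each
family's source inside the chest, feeding per-breath aggregate features
(quadrant counts and their six pairwise percentage differences, maximum
inter-crackle distances).

Classification is hierarchical: an SVM or neural network labels
individual crackles; breaths are labelled by majority vote over their
crackles (optionally fused with the aggregate features by a
second-stage model); patients by majority vote over breaths — evaluated
with patient-stratified five-fold cross-validation.

## A worked example

```r
library(cracklelab)

rec <- synthesize_recording(builtin_profile("CHF"), seed = 1)
rec
#> <crackle_recording> CHF profile, seed 1
#>   20.0 s x 16 channels at 8000 Hz, 3 breaths, 38 crackles

ex <- extract_recording(rec)
nrow(ex$crackles)                 # crackle families found
#> [1] 37
round(mean(ex$crackles$ctc), 1)   # measured transmission, %
#> [1] 20.2
round(mean(ex$crackles$pitch))    # measured pitch, Hz
#> [1] 271
round(mean(ex$crackles$zxs), 1)   # baseline crossings per crackle
#> [1] 6.3
```

Thirty-eight annotated crackles were synthesized and thirty-seven
crackle families recovered (one lost to the four-half-period validity
rule). The measured transmission sits near the CHF profile's nominal
23% — this is the group whose crackles transmit widely; an IPF
recording lands near 16% — while the measured pitch is within this
patient's draw around the profile's 302 ± 64 Hz and the crossing count
reflects its ~5-half-period crackles.

The numbered scripts under `analysis/` run the full study on a
demonstration cohort: `01_simulate_cohorts.R` simulates and measures
36 patients and writes the per-crackle/per-breath/per-patient tables
under `results/`; `02_group_statistics.R` produces the group-comparison
table (means ± SD with Welch t-tests of IPF against CHF and PN);
`03_classification.R` runs the cross-validated hierarchical
classification and writes the metrics tables.

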