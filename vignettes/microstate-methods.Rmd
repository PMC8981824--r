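---
title: "Microstate analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the segmentation model and its assumptions, the synthetic-data model and
what it does and does not emulate, the tunable parameters with their
defaults, and the places where the design was genuinely open and a choice
had to be made.

## 1. The segmentation model

Multichannel resting-state EEG is modelled, instant by instant, as a scalar
amplitude times one of a small number of fixed scalp topographies.  The
analysis estimates those topographies and the hidden class sequence.

**Average reference.** All topographic quantities are defined after
re-referencing each sample to its instantaneous channel mean; every map in
the package is average-referenced and unit-normed, so the spatial (Pearson)
correlation between maps is simply their inner product.

**GFP and GFP peaks.** The global field power, the spatial SD across
channels, measures the momentary strength of the field.  Topographic
signal-to-noise is best at GFP peaks, so clustering uses only peak
topographies (`find_gfp_peaks()`: strict local maxima within epochs, a
10 ms minimum separation with conflicts resolved in favour of the larger
peak and ties toward the earlier sample; all peaks are used, no cap).

**Polarity invariance.** Spontaneous EEG topographies reverse sign with
the oscillatory phase while the generating configuration stays the same,
so the entire chain — clustering, labelling, back-fitting, GEV — treats a
map and its negation as identical.  This is the defining "modification" of
the K-means used: assignment by *squared* spatial correlation, and the
cluster update is the dominant eigenvector of the assigned topographies'
outer-product sum rather than their arithmetic mean.

**Objective and convergence.** The clustering objective is the global
explained variance (GEV); the assignment and eigenvector steps each cannot
decrease it, and a run stops when the relative GEV change falls below
`tol` (default 1e-8) or after `max_iter` (500) iterations.  The best of
`restarts` (default 50) random initialisations — `k` distinct observed peak
topographies — is kept.  `k` is fixed at 4, the canonical A–D solution;
the package deliberately does not cross-validate `k`.

**Two-level group maps.** Subject maps are clustered per subject, then
aggregated per group (`aggregate_group_maps()`): subjects' map sets are
permuted so corresponding maps line up, each group slot is re-estimated as
the dominant eigenvector across subjects, and the two steps alternate
until the mean squared spatial correlation (the common variance across
participants) stops improving.  The criterion is *maximised*; the
alternative reading (minimisation) would anti-align subjects and has no
sensible fixed point.  For small problems (`k!^n <= 4096` configurations)
the alignment is solved exhaustively; the iterative scheme with random
restarts is used beyond that, because the alternation alone can stall in
local optima on weakly structured maps (the test suite checks it against
a brute-force oracle).  Single-level pooled clustering is available by
concatenating subjects' peaks and fitting once.

**Canonical labelling.** Group (and subject) maps are assigned the labels
A–D by the permutation maximising the summed absolute correlation with the
package's canonical template maps, ties broken by the lexicographically
smallest permutation, with signs aligned afterwards.

## 2. Back-fitting and the trough problem

Temporal parameters require a label for *every* sample, not just peaks.
Two conventions are implemented (`backfit()`):

- `"sample"`: instantaneous argmax of the absolute spatial correlation.
  This is exact on noise-free data and is the cleanest mathematical
  definition, but it is fragile in exactly one place: at GFP troughs the
  field passes through a polarity reversal, the topography vanishes, and
  any noise whatsoever relabels those samples.  Each such event splits a
  run in two, so mean durations are *systematically* underestimated even
  when per-sample agreement is high — an estimated 97% agreement can
  coexist with a 2–3× inflation of run counts.
- `"peaks"` (the pipeline default): labels are computed at GFP peaks and
  every sample inherits the label of its nearest peak, which places
  microstate boundaries at GFP troughs.  This is the standard segmentation
  convention for spontaneous EEG and is robust by construction: the peak
  topographies are the highest-SNR samples available.

Zero-variance samples (possible only in degenerate inputs) inherit the
previous sample's label; a leading flat stretch gets class A.

`smooth_labels()` provides the plug-in style short-segment rejection
(samples of a sub-threshold run are reassigned to whichever flanking class
correlates better, repeated to convergence).  It defaults to off: on
synthetic data it is unnecessary under the `"peaks"` convention, and
leaving it off preserves exact recovery semantics.  Epoch-truncated runs
are *included* in duration and occurrence by default, which keeps the
identity `occurrence x duration = coverage` exact per subject and class; a
flag excludes them for users who prefer the stricter convention.

Transition syntax counts ordered changes between consecutive runs within
an epoch (never across epoch boundaries) and normalises all 12 ordered
pairs jointly to 100 — the convention under which the package's reference
transition table is (to rounding) self-consistent.

## 3. The synthetic-data model

The generator (`semi_markov_spec()`, `sample_state_sequence()`,
`render_eeg()`, `generate_cohort()`) emulates 64-channel, eyes-closed,
4-minute recordings analysed at 500 Hz:

- **Dynamics.** Segment classes follow an embedded (zero-diagonal) Markov
  chain; `segment_weights` must be its stationary distribution (checked to
  0.02 at construction), which makes durations, occurrences, coverages and
  joint transition percentages mutually consistent.  Segment lengths are
  gamma with shape 2 — a right-skewed law whose spread matches the
  conventional 60–120 ms description of microstate lifetimes.
- **Boundary lattice.** Durations are rounded probabilistically to the
  50 ms half-period lattice of the carrier (mean preserved *exactly* by an
  internal calibration of the gamma mean), so segment boundaries coincide
  with polarity reversals of the dominant rhythm.  This mirrors the
  empirical observation that topographies are stable around GFP peaks and
  switch at GFP troughs, guarantees every segment contains at least one
  GFP peak, and keeps the rendered signal free of broadband switching
  transients that the 2–20 Hz analysis filter would otherwise smear over
  ~50 ms (the smearing was measured to bias recovered durations by tens of
  percent).  `align_ms = 0` disables the lattice for users who want free
  gamma durations.
- **Carrier.** The rendered data are `a(t) * T_label(t) + noise` with
  `a(t)` a phase-continuous 10 Hz sinusoid of unit mean absolute
  amplitude, offset by half a sample so its zero-crossings fall between
  samples.  The GFP waveform is therefore a rectified 10 Hz sinusoid with
  peaks every 50 ms (~20 peaks/s).  The carrier is kept *signed* rather
  than rectified: rectification would move the envelope's spectral content
  to DC and 20/40 Hz — outside or at the very edge of the 2–20 Hz band —
  whereas the signed carrier sits at 10 Hz, mid-band, and all downstream
  analysis is polarity-invariant anyway.
- **Noise and SNR.** Spatially and temporally white Gaussian noise,
  re-referenced to the average, scaled so mean signal GFP over mean noise
  GFP equals `snr` (default 5).  The definition is scale-free, avoiding
  any commitment to microvolt calibrations.
- **Templates.** Canonical maps are differences of two isotropic Gaussian
  bumps (sigma 0.6 head radii) on an azimuthal-equidistant projection of a
  64-channel 10-10 montage (shipped as a packaged CSV): two mirror-image
  diagonal dipoles (A, B), an occipital–frontal pattern (C), and a
  fronto-central maximum against a broad posterior negativity (D).
  Reflecting the montage exchanges A and B exactly; pairwise spatial
  correlations are well below the 0.95 collinearity bound (max ~0.62, as
  in real canonical maps, which are themselves far from orthogonal).
- **Cohort and clinic.** Per-subject class-C mean durations are jittered
  (Gaussian, SD 8.70 ms by default) and a headache-impact score is drawn
  from the conditional Gaussian giving population correlation `rho`
  (default −0.27) with that planted duration, for the patient group only;
  age and sex are filled from the reference demographics.  One master seed
  is split deterministically into per-subject seeds, so cohorts are
  reproducible subject by subject.

**What the generator does not emulate.** Real EEG is full-rank with many
simultaneous sources, 1/f background, alpha reactivity, blinks, muscle and
line noise; topographies drift within a microstate rather than being
exactly constant; and microstate boundaries are only statistically — not
deterministically — tied to GFP troughs.  Passing the recovery tests
therefore demonstrates the *correctness of the estimators* under the
stated generative model, not robustness of microstate analysis to
real-world artifacts (which the study's own preprocessing handles by
visual rejection and ICA, out of scope here; an amplitude-threshold
epoch-flagging hook, `flag_epochs()`, is the provided pass-through).

## 4. Preprocessing

Zero-phase forward–backward Butterworth filtering (4th-order band-pass,
i.e. two poles per edge; RBJ biquad notch with quality 30 — hand-derived,
as the signal-processing library exposes no notch designer), applied as in
the reference chain: 0.5–70 Hz plus 50 Hz notch at the acquisition stage,
2–20 Hz before microstate analysis.  Downsampling is anti-aliased
(IIR decimation for integer factors, polyphase resampling otherwise).
Epoching takes the first N contiguous 2 s epochs in temporal order — the
selection criterion for "artifact-free" epochs in real data is a human
judgement that synthetic data does not need — and applies the common
average reference per sample.

## 5. Group statistics

The 2 (group) × 4 (class) mixed ANOVA is fitted through the multivariate
linear-model route (`car::Anova`, type III, sum-to-zero group coding) —
the standard computational path for this design — and reports F, the
uncorrected and Greenhouse–Geisser-corrected p (always, with epsilon from
the pooled within-subject covariance), and Mauchly's sphericity test,
whose p < 0.05 flags when the corrected p is the one to read.  A
hand-built split-plot projection oracle in the test suite confirms the
F statistics on balanced designs.

Simple effects are per-class pooled-variance t-tests with df = N − 2 (the
printed df in the reference results identify the pooled, not Welch,
test); an ANOVA-pooled-error variant was considered and set aside as the
reference's df are equally consistent with the independent version.
Transition tests are 12 pooled t-tests with Bonferroni m = 12.  The 2 × 2
chi-square applies the Yates continuity correction by default — the
corrected statistic is the one consistent with the reference value, and
the correction approximates the fixed-margin permutation null, as the
test suite verifies by Monte-Carlo.  TANOVA L2-normalises each subject's
maps and compares groups by the GFP of grand-mean difference maps (group
effect: after averaging maps within subject; interaction: class-wise
differences after removing the group means), with `p = (1 + #{perm >=
obs}) / (1 + n_perm)` under subject-label reassignment (default 5000
permutations).

## 6. Numerical choices and degenerate inputs

- Spatial correlations with a zero-variance vector are defined as 0.
- K-means assignment ties go to the lowest map index; labelling ties to
  the lexicographically smallest permutation; peak ties to the earlier
  sample.
- Eigenvector updates use the symmetric eigendecomposition of the C × C
  scatter (cheaper than an SVD of the tall topography matrix and
  numerically equivalent for the dominant vector).
- The permutation p floor `1/(n_perm + 1)` is enforced by the +1
  convention; TANOVA requires at least 100 permutations and 2 subjects
  per group.
- Degenerate requests error early with informative messages: durations
  unresolvable at the sampling rate, non-stationary segment weights,
  upsampling, bands at or above Nyquist, k exceeding the peak count,
  all-zero topographies, missing ANOVA cells.

## 7. Problem sizes used in validation

The test suite validates parameter recovery end-to-end on a 20-subject
cohort at the full reference recording conditions (4 min, 500 Hz, 64
channels, snr 5, 50 restarts) — planted class-C duration, class-D
occurrence, class-C coverage and the D→B transition cell are recovered
within their 5% / 0.5-point tolerances — and on a 3-subject, 2-minute
cohort for the faster structural checks.  The TANOVA type-I simulation
uses 400 null cohorts at 199 permutations (the three-sigma binomial band
at that scale is 0.02–0.08); the clinical-correlation recovery uses 200
replicates at n = 61.  These sizes were chosen so that Monte-Carlo error
is comfortably inside each tolerance.

## 8. Known limitations

- The canonical templates are analytic surrogates; they resemble the
  published class topographies qualitatively but are not estimated from
  any real dataset, and labelling real maps against them should be
  reviewed visually.
- The rank-1-per-instant signal model makes GFP troughs exactly singular;
  real data are better conditioned there, so the `"sample"` backfit mode
  is less fragile on real recordings than on synthetic ones — but the
  `"peaks"` convention remains the recommended default for both.
- No source localisation, no alternative clusterings (AAHC, PCA, HMM),
  no entropy-based syntax measures, and no EDF I/O (recordings exchange
  as matrix CSV plus montage CSV).
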