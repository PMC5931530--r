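---
title: "Nonlinear dynamical biomarkers from infant EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear dynamical biomarkers from infant EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

Infants at high familial risk of autism spectrum disorder (an older
sibling with ASD) can be followed from the first months of life, but a
behavioral diagnosis is only reliable from around 18–36 months. The
pipeline in `eegdyn` asks whether the *dynamics* of resting-state EEG —
not band power, but measures of regularity, determinism and long-range
correlation — carry an earlier signal. Three outcome groups are modeled:
low-risk controls without ASD (`LRC-`), high-risk infants without ASD
(`HRA-`), and infants diagnosed with ASD, each subject carrying an ADOS
Calibrated Severity Score (CSS) on a 1–10 scale, with 4 the conventional
diagnostic boundary.

The pipeline is:

1. **Ingest** (`read_edf`, `select_montage`, `resample_to_250`,
   `extract_segment`): EDF recordings, reduced to the 19-channel 10–20
   montage in a fixed order, at 250 Hz (500 Hz data are anti-alias
   filtered and decimated), using the leading 30-s segment with no
   splicing or data-driven selection.
2. **Band decomposition** (`wavelet_bands`): six dyadic frequency bands
   per channel from the detail series of a 6-level Daubechies-4 discrete
   wavelet transform. Level k nominally covers (fs/2^(k+1), fs/2^k]; the
   conventional EEG labels (delta … high gamma) name these power-of-two
   bands rather than the clinical definitions.
3. **Nonlinear measures** (`channel_band_measures`): nine scalars per
   sensor/band cell — the seven recurrence-quantification statistics
   (RR, DET, LAM, L_max, L_entr, L_mean, TT), sample entropy, and the
   DFA scaling exponent — giving the 19 × 6 × 9 = 1026-feature vector
   per session (`extract_features`), or 2052 when two visit ages are
   concatenated (`combine_ages`).
4. **Prediction** (`loo_predict`): an RBF-kernel SVM trained on ASD and
   LRC- subjects under leave-one-out cross-validation, with recursive
   feature elimination inside every fold; HRA- subjects are scored by
   the full ASD/LRC- model. The signed decision-function value is mapped
   affinely to a severity estimate in [1, 10]; estimates in the open
   interval (3.5, 4.5) are "uncertain". Significance is assessed by
   re-running the identical pipeline under label permutations
   (`permutation_pvalue`).
5. **Description** (`difference_map`, `regional_trajectory`): Welch
   t-test difference maps per measure with the Bonferroni gate
   p < 5 × 10⁻⁵ (0.05 over 1026 features, stored as the literal
   constant), and regional developmental trajectories with bootstrap
   confidence bands.

## Measure definitions and conventions

**Recurrence quantification.** Each band series is delay-embedded
(default m = 3, τ = 1) and two states are recurrent when their max-norm
distance is within ε = 0.2 × SD of the series. The line of identity is
excluded from the recurrence rate and line statistics (Theiler window 1).
With the diagonal line-length histogram P(l) over maximal runs,
DET = Σ_{l≥2} l·P(l) / Σ_{l≥1} l·P(l); L_mean and L_entr are the mean and
Shannon entropy of the l ≥ 2 distribution and L_max the longest run; the
vertical analogues give LAM and TT. Note that single recurrence points
count in the denominators: a fully recurrent plot has DET slightly below
1 because its corner cells form length-1 diagonals. Embedding parameters
and thresholds are nowhere canonical for infant EEG; the defaults are the
common RQA conventions, are recorded in every result's settings, and are
configurable (`nld_settings`). Whether a fixed radius or a fixed
recurrence rate is preferable is an open question; this implementation
uses a fixed SD-scaled radius and records it.

**Sample entropy.** −ln(A/B) with template length m = 2 and tolerance
0.2 × SD under the Chebyshev norm, self-matches excluded, the template
convention that counts both lengths over the first N − m starting
positions. Degenerate cases (a constant band, or no template matches)
return a NaN sentinel with a reason attribute rather than an error, so a
single flat channel cannot abort a 1026-feature extraction; sentinels are
median-imputed later, inside classification folds only.

**DFA.** The mean-centered series is integrated, split into
non-overlapping boxes, linearly detrended per box, and the slope of
log RMS fluctuation against log box size is returned over 8 log-spaced
box sizes from 16 to N/4. On exact fractional Gaussian noise the
estimator recovers H ∈ {0.3, 0.5, 0.8} at N = 7500 with mean absolute
error well under 0.07 (tested).

**Computation window.** RQA and sample entropy are O(N²); they are
evaluated on the leading `max_points` samples of each band series
(default 2000 ≈ 8 s at 250 Hz), a standard windowing practice for
recurrence analysis of EEG, while DFA uses the full series where its box
hierarchy needs the length. The window is a setting, not a constant.

**Wavelet details.** The transform is the periodized orthogonal DWT with
the published 8-tap Daubechies-4 filter; signals are reflected at the end
to the next multiple of 2⁶ and reconstructions cropped back. Periodization
keeps the transform exactly orthogonal, so coefficient energy equals
signal energy and the six reconstructed details plus the approximation
reconstruct the input to machine precision — both are tested invariants.
Each detail is reconstructed to full signal length so the nonlinear
measures see equal-length series in every band (the alternative — raw
decimated coefficient series of different lengths per level — would make
measures incomparable across bands). The multiscale coarse-graining
procedure is provided as well (`coarse_grain`); under averaging
normalization it is *identical* to Haar approximations
(`haar_approximation`), which is why dyadic wavelet detail bands are the
natural frequency decomposition for multiscale entropy work; the
orthonormal 1/√2 Haar convention is available behind a flag.

## The classification protocol in detail

Every fold pipeline fits, in order and strictly on training rows: median
imputation of sentinel cells, z-scoring, recursive feature elimination,
the RBF SVM, and the affine severity map. Feature elimination needs
per-feature importances which an RBF kernel does not expose, so ranking
uses the squared hyperplane weights of a linear-kernel SVM while the
predictions come from an RBF SVM refit on the selected subset — the only
composition consistent with pairing RFE with an RBF classifier. The
halving schedule (p, p/2, …, 16) is scored by a deterministic stratified
3-fold internal CV (round-robin fold assignment, no RNG), taking the
smallest subset at the best score; a fixed subset size can be requested
instead (`n_features`), which the permutation analyses use for a constant
workload across 101 pipeline runs. SVM hyperparameters are the library
defaults throughout.

The decision-function value of libsvm is the signed distance to the
separating surface up to the margin normalization; since the severity map
is an affine fit of training CSS on training distances, the scale factor
is absorbed and only the sign convention matters (positive = ASD side,
enforced explicitly). Severity estimates are clipped to [1, 10]. A
min-max style map would also be defensible; the least-squares fit was
chosen because it uses every training pair rather than the two extremes.
Distances are taken per LOO fold, not from a single full-cohort model.

Binary labels follow the clinical rule (ASD iff estimate ≥ 4), which also
resolves the tie at decision value exactly 0; with the uncertainty zone
active, estimates in (3.5, 4.5) are reported as "uncertain" and excluded
from the (c)-style metrics with their count reported.

The permutation p-value is the add-one estimator
(1 + #[acc ≥ acc_obs]) / (1 + n_trials): with 100 trials and no shuffle
reaching the observed accuracy it reports 1/101 ≈ 0.0099, never exactly
zero. Each subject's label and severity score travel together under the
shuffle.

## The synthetic cohort generator

The study's raw infant EEG is not publicly releasable, so the package
carries a generator (`generate_recording`, `generate_cohort`) that
emulates the *statistical structure the analysis assumes* rather than
biophysical EEG. Each channel is unit-variance fractional Gaussian noise
(exact Davies–Harte simulation; baseline H = 0.55, in the range DFA
estimates report for resting EEG) scaled to ~20 µV rms. Channels listed
in the effect cells additionally carry a deterministic oscillatory
component: a tone at the cell band's center frequency with slow random
phase drift, projected onto the cell's own wavelet-detail subspace so
that the planted component re-decomposes entirely into its designated
band (a raw tone would leak filter side-lobes into neighboring cells,
smearing a cell-level effect across the band axis). Its amplitude
grows with the subject's severity score
(amp = effect_size × (0.2 + 1.3 × (css − 1)/9) in units of noise SD),
and their noise H shifts upward with the latent group
(0.15 × effect_size per unit group level; configurable via
`hurst_shift`, set it to 0 to confine the effect strictly to the listed
cells). An fGn + tone mixture is used because the two components provably
move the measures in opposite directions: adding deterministic structure
lowers sample entropy and raises determinism and laminarity, while
raising H lifts the DFA exponent — exactly the contrast space the
analysis works in.

Default effect cells are T7/T8/P4/P8 in beta and gamma plus O1/O2 in
delta, mirroring the temporal, temporal-parietal and posterior regions
where infant-EEG group differences in SampE and DET are most consistently
described. Severity scores are drawn uniform on [1, 2.5] (LRC-), [1, 5]
(HRA-), and [4, 10] (ASD): ASD severity is never below the diagnostic
boundary of 4, and the high-risk non-ASD group overlaps both neighbors,
reproducing the borderline cases that make that group hard to classify.
An optional `age_flip` reverses the group contrast from 12 months on,
emulating a developmental crossover; it is off by default. With
`effect_size = 0` the generator is an exact null: group and severity have
no influence whatsoever, which the calibration tests exploit.

Within-group feature variance of real cohorts is not characterized
anywhere; the generator's noise scales are therefore free design
parameters chosen once (above), and results on synthetic cohorts
deliberately make *protocol-level* claims (separability, calibration,
no leakage) rather than claims of reproducing any clinical accuracy
table. What passing tests show is that the machinery is correct and
calibrated; what they cannot show is performance on real infant EEG,
with its artifacts, nonstationarity, inter-site montage variation and
far messier group structure.

## Numerical and degenerate-input choices

* EDF I/O quantizes against the header-precision physical range, so a
  write/read round trip is exact to one 16-bit quantization step; files
  shorter than their declared record count fail naming the first
  incomplete record; mixed per-channel rates are rejected.
* High-density nets are reduced by explicit label match or a
  user-supplied alias table; there is no positional nearest-sensor
  guessing.
* Bands whose SD is ≤ 1e-10 (e.g. details of a flat channel, zero up to
  rounding) are treated as degenerate: their measures are NaN sentinels,
  flagged in the feature vector's sentinel mask.
* Empty recurrence-line histograms yield zeros plus a degenerate flag
  rather than errors.
* Zero-variance columns z-score with σ = 1; zero-variance training
  distances make the severity map an error (the caller's fold is
  unusable, and silently returning a constant would hide it).
* All stochastic steps (cohort draws, permutation shuffles, bootstrap)
  take explicit integer seeds and restore the caller's RNG state.

## Simulation scales used by the test suite

The acceptance-style tests run the full pipeline at sizes chosen for a
single-CPU desk run: the separable-cohort protocol check uses 20
subjects per group with 8-s recordings and a 1000-sample analysis
window; permutation calibration under the null uses 20 repeats of 4+4
cohorts with 2-s recordings; difference-map recovery uses 20 planted
cohorts of 15+15 (2-s recordings) and 30 null cohorts of 30+30 (1-s
recordings) with per-cell sample entropy. The acceptance script uses the full study
conditions (30-s recordings, default settings) for its cohort. These
sizes are stated here because they are the package's chosen simulation
scale; the measures and protocol code are identical at every scale.

## Known limitations

* The generator makes no attempt at biophysical realism (no 1/f
  background mixture per band, no blinks or muscle artifacts, no
  volume-conduction correlation between neighboring sensors).
* Recurrence statistics depend materially on the embedding and threshold
  conventions; comparisons with other RQA software require matching
  those settings cell-for-cell.
* The severity map is affine in the decision value; real
  distance-to-severity relations need not be linear.
* The spectral-power feature family is deliberately out of scope: the
  pipeline is about dynamics, and power features are excluded by design.
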