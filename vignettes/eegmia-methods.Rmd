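---
title: "Multiscale information analysis of high-frequency EEG oscillations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{eegmia methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`eegmia` extracts complexity- and decomposition-based features from
trial-structured multichannel EEG and evaluates them with a per-subject
cross-validated SVM. This vignette explains the procedure, the parameters
that matter, the numerical choices behind the implementation, and what the
package's synthetic-data tests do and do not establish.

## Data model and preprocessing

A *recording* is one trial: a channels-by-samples matrix in microvolts
with a sampling rate and 10--20 montage labels. Trials carry a
valence/arousal self-assessment on the 1--9 scale; ratings strictly above
5 count as High, 5 or below as Low, partitioning the plane into the HVHA /
LVHA / HVLA / LVLA quadrants used as class labels. The boundary is
deliberately inclusive on the low side so that the partition is exact.

Trials are cut into non-overlapping 20-s *samples* (at the full study
geometry, 60-s trials at 512 Hz give three samples of 10,240 points);
a trailing partial window is discarded. Preprocessing is a 50 Hz notch
(second-order constrained biquad, quality factor 30) and a 0.3--100 Hz
Butterworth band-pass of order 4, both applied forward--backward
(`filtfilt`) for zero phase. The notch order and quality factor, and the
band-pass order, are implementation choices pinned down by testable
contracts: at least 20 dB attenuation on the target tone, passband
distortion under 1 dB beyond 5 Hz from the notch. An optional
EOG-removal hook accepts any channel-matrix transform (for example an
ICA-based cleaner); the default is a pass-through, since no
component-selection rule is part of the method itself.

The two analysis branches see different preprocessing: the time-domain
(multiscale entropy) branch uses the fully filtered signal, while the
EEMD branch uses the notch-only signal — the decomposition itself
separates low-frequency artifact modes, and band-passing first would
remove the very modes the decomposition is supposed to isolate.

## Time domain: MSE and MECI

Sample entropy `SE(m, r) = -log(A/B)` counts template pairs within
tolerance `r` under the Chebyshev metric, excluding self-matches, with
both the length-`m` and length-`(m+1)` counts taken over the same
`N - m` templates. Defaults `m = 2`, `r = 0.15` (of the SD of the series
under analysis) are the standard physiological-series settings. When no
`(m+1)`-length pair falls within tolerance the estimate is undefined; the
package returns `NA` (a sentinel that propagates into feature matrices
and excludes the affected rows at training time) rather than failing a
batch.

Coarse-graining replaces the series by means over non-overlapping windows
of length `tau`; the multiscale entropy curve is the sample entropy of
each coarse-grained series for `tau = 1..s` (50 scales at 512 Hz). Scale
`tau` analyses frequencies around `fs / (2 tau)`, so scales 1--5 at
512 Hz cover the band above 51.2 Hz, truncated at 100 Hz by the
band-pass — the high-frequency oscillations. The multiscale EEG
complexity index (MECI) is the area under the curve over scales 1--5,
computed as the plain sum of the per-scale entropies (a trapezoid option
exists, but the sum is canonical and makes MECI exactly additive over
disjoint scale ranges).

Two tolerance conventions are exposed. The default recomputes
`r = 0.15 x SD` from each coarse-grained series (`r_mode = "per-scale"`);
the alternative fixes the absolute tolerance from the scale-1 series
(`r_mode = "original"`). The distinction matters for interpretation:
coarse-grained white noise stays Gaussian, so under the per-scale
convention its MSE curve is nearly flat, whereas under the original-SD
convention the variance shrink (proportional to `1/tau`) drives the
well-known decreasing white-noise curve. The package's
decreasing-curve checks therefore use the original-SD mode; features use
the per-scale default.

## Frequency domain: EMD, EEMD, and entropies

Empirical mode decomposition sifts each series into intrinsic mode
functions: cubic-spline envelopes through the local maxima and minima,
subtraction of the mean envelope, repeated until the candidate satisfies
the IMF conditions. Numerical choices:

* **Envelopes.** Natural cubic splines through the extrema, with two
  extrema mirrored beyond each boundary before fitting; this suppresses
  end swings without inventing data.
* **Stop rule.** A Cauchy-type criterion
  (`sum((h_prev - h)^2) / sum(h_prev^2) < 0.2`) plus the
  extrema/zero-crossing condition (counts differing by at most 1), capped
  at 10 sifting passes. Extra passes (up to 5 times the cap) are spent
  only while the extrema/zero-crossing condition is still violated, so
  every accepted IMF honours it; in practice white-noise-like inputs
  accept within the first ten passes.
* **Depth.** Decomposition stops at `max_imfs` or when the remainder has
  fewer than two maxima or minima. The pipeline default depth is 11 IMFs
  for 20-s samples; the dyadic rule `floor(log2(N)) - 1` is exposed as
  `imf_count_formula()` for reference. Because extraction is strictly
  sequential, truncating the decomposition at the feature IMF (index 2 by
  default) leaves IMFs 1--2 bit-identical to a deeper run; the feature
  builder exploits this for speed.
* **EEMD.** Gaussian white noise with SD `0.1 x SD(x)` is added in each
  of 100 ensembles (the defaults), each noisy copy is decomposed, and
  IMFs are averaged index-wise; ensembles that stop early are zero-padded
  before averaging, with a logged message. All noise comes from one
  master seed, drawn once as a matrix so runs are bit-reproducible and the
  caller's RNG state is untouched. Averaged IMFs no longer reconstruct the
  input exactly; the residual shrinks as `1/sqrt(ensembles)`.

Per-IMF features are the energy (sum of squares, not normalised) and
fuzzy entropy. Fuzzy entropy compares mean-removed templates with the
continuous membership `exp(-d^n / r)` (`m = 2`, `r = 0.15`, `n = 2`,
lag 1), giving an estimator continuous in `r` where sample entropy's hard
threshold jumps. The printed definition of the final difference contains
a doubled logarithm, which the implementation treats as a typographical
slip: it computes `ln(phi_m) - ln(phi_m1)`, the only reading for which a
constant series yields exactly zero. Tolerances are interpreted on
*normalised* data: with the default relative mode the series is
standardised to unit SD before comparison, which is also the only reading
under which the `exp(-d^2/r)` membership is scale-invariant. Renyi
entropy of order 2 is computed from a Gaussian kernel density evaluated
at the sample points and normalised to a probability vector;
the bandwidth default is Silverman's rule `1.06 SD n^(-1/5)`. Whether
those probabilities should instead be bin integrals is not determined by
the method description; the at-sample-points choice is documented here
rather than asserted as the only one. A discrete-probability entry point
(`renyi_entropy_discrete`) exposes the bare formula. All logarithms in
the package are natural.

For plotting-style summaries of entropy distributions,
`entropy_confidence_bounds()` min--max maps values to `[0, 0.99]`,
applies the Fisher Z-transform, forms a normal-theory 95% interval on the
Z scale, and maps back; identical inputs give a zero-width interval.

## Classical comparison features

* **Box-counting fractal dimension**: the curve is normalised into the
  unit square, occupied boxes counted at dyadic sizes `2^-2 .. 2^-7`, and
  the dimension is the least-squares slope of log-count versus
  log-inverse-size. Constant series return 1 by convention.
* **Windowed sample entropy**: non-overlapping 512-point windows,
  arithmetic mean over windows with a defined value.
* **db4 band energies**: the signal is resampled to 128 Hz so the dyadic
  detail bands of a 5-level periodised Daubechies-4 decomposition align
  with the canonical EEG bands (d1 = 32--64 Hz covers the 32--45 Hz gamma
  band after the 45 Hz-limited prior filtering, d2 = 16--32 Hz is beta).
  A detail level is selected for a requested band when their overlap
  covers at least half of the narrower band. No maintained wavelet
  package ships with this R installation, so the transform is a direct
  periodised orthogonal filter bank; orthogonality is verified by an
  energy-conservation (Parseval) test. The analysis rate and depth are
  configurable since the original band table's sampling rate is not
  dictated by the method.

## Evaluation protocol

Feature matrices hold one row per 20-s sample and `feature x channel`
columns (3 features per channel for MIA, 4 for the classical set). The
classifier protocol:

* **Folds are grouped by trial**: all segments of one trial fall in the
  same fold, and trials are stratified by class across folds. This is the
  only reading of "no leakage between training and testing" that also
  permits per-subject models; splitting segments of one trial across the
  boundary would leak trial identity.
* **Scaling**: per-column min--max to `[-1, 1]`, fitted on the training
  fold only and applied to the test fold (values outside the training
  range extrapolate linearly). Fitting on the pooled folds — as a literal
  reading of scaling "training and testing sets" together suggests —
  leaks test statistics into training; that variant remains available
  behind `scaling = "joint"` for comparison, but the non-leaking variant
  is the default.
* **Model**: RBF-kernel one-versus-one SVM (libsvm via e1071, the same
  code path as the original LIBSVM toolchain), `k(k-1)/2 = 6` pairwise
  machines for four classes, majority vote with libsvm's internal tie
  handling. Cost and gamma come from an inner 5-fold grouped grid search
  over `2^{-5..15}` and `2^{-15..3}` (log-spaced, step 4); the search
  ranges are implementation choices, as the method names only the search
  procedure.
* **Metrics**: pooled confusion matrix with predicted classes in rows,
  per-class precision / recall (sensitivity) / specificity, unweighted
  macro averages, and overall accuracy as the mean of per-fold
  accuracies. Empty rows or columns yield `NA` metrics rather than zeros.
  Per-class decision scores (signed sums of pairwise decision values)
  feed one-versus-rest ROC curves; the participant AUC is the mean of the
  per-class AUCs. Under this construction chance level is 0.5 per class;
  a four-way reference line at 0.25 would correspond to a different ROC
  construction that the package does not reproduce.
* **Channel/region statistics**: for each channel and feature, class
  differences are tested with one-way ANOVA if every group passes a
  Lilliefors normality check and Levene's variance-homogeneity check at
  alpha 0.05, otherwise Kruskal--Wallis (groups smaller than four route
  directly to the rank test, which needs no normality assumption). Counts
  of significant (feature, subject) pairs per channel are summed over the
  five scalp regions; the 32-channel montage partition used is frontal
  {Fp1, Fp2, AF3, AF4, F7, F3, Fz, F4, F8}, central {FC5, FC1, FC2, FC6,
  C3, Cz, C4}, temporal {T7, T8}, parietal {CP5, CP1, CP2, CP6, P7, P3,
  Pz, P4, P8}, occipital {PO3, PO4, O1, Oz, O2}.

## The synthetic generator

The generator emulates the *geometry and class structure* of a
trial-based affective EEG study, not real electrophysiology. Per trial
and channel it sums:

* a `1/f^beta` Gaussian background (default SD 8 uV, `beta = 1.5`),
* a 51--100 Hz component: a MIX-style blend
  `(1 - w) x sinusoid + w x band-limited noise`, scaled to
  `6 uV x gain`, where the *arousal* class sets the gain (2 for high
  arousal, 1 for low) and the *valence* class sets the noise fraction
  `w` (0.85 for high valence, 0.2 for low),
* a 50 Hz line sinusoid (2 uV) motivating the notch, and
* sub-10 Hz raised-cosine EOG-like transients (4 per minute, ~100 uV,
  0.3--0.6 s).

Ratings are drawn uniformly inside the intended quadrant (High in
[5.5, 8.5], Low in [1.5, 4.5]), so every label round-trips through the
quadrant assignment. Everything is deterministic given the config seed.

Two design points deserve emphasis. First, the background exponent and
component amplitudes were chosen, once, so that the high band is
dominated by the class component: with a shallower (`beta = 1`)
background, the broadband background itself out-randomises the band-
limited component and *adding* high-band signal lowers whole-signal
entropy, inverting the intended ordering. With the defaults, MECI and
IMF2 fuzzy entropy order the classes HVHA highest to LVLA lowest, and the
effect is statistically recoverable at 30 trials per class — the
generator's own regression test. Second, because the four classes are
separable *by construction* in amplitude and irregularity, classical
band-energy features also separate them (on synthetic runs the classical
set can even reach higher accuracy than the MIA set). Passing the
end-to-end tests therefore demonstrates that the pipeline recovers
injected class structure without leakage — it does not reproduce the
relative ranking of MIA versus classical features on real EEG, which
depends on properties of real recordings the generator does not model
(topography, non-stationarity, cross-channel structure, genuine
artifact statistics).

## Problem sizes and runtime

The package's own evaluation runs at a desk scale chosen to exercise
every stage in minutes on one CPU: 8 channels at 256 Hz, 120 trials of
20 s (one sample per trial, 30 trials per class), EEMD with 20 ensembles.
Oracle-equivalence tests compare the C++ entropy kernels against
brute-force R evaluations on series of 100--300 points; decomposition
identities run on hundreds of seeded inputs; the significance-routing
calibration uses 500 null draws. The full-scale configuration (32
channels, 512 Hz, 100 ensembles, 50 scales) is the package default for
real data and is exercised structurally (bookkeeping, shapes, identities)
rather than end-to-end in the tests.

## Known limitations

* EEMD averaging changes IMF counts across ensembles near the
  decomposition floor; zero-padding is logged but the deepest averaged
  IMFs should be interpreted with care.
* The EDF/BDF reader supports continuous same-rate signal layouts only
  (no annotations, no mixed rates).
* The Renyi estimator evaluates kernel densities at sample points; for
  heavy-tailed data a binned or integrated estimator may behave
  differently.
* One-versus-one tie handling is delegated to libsvm; alternative
  tie-breaks (for example by summed decision values) would require a
  reimplementation of the voting layer.
* The generator's EOG transients are additive and channel-independent;
  nothing in the package validates ICA-based artifact removal.
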