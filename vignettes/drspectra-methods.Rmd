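---
title: "Methods: tissue differentiation from diffuse reflectance spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue differentiation from diffuse reflectance spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Surgical procedures near the facial nerve would benefit from an intraoperative
signal that tells nerve apart from the tissues that surround it — salivary
gland, cortical bone, and the blood-rich cancellous bone. Visible-range
diffuse reflectance spectroscopy is a candidate: broadband light is delivered
through a fiber probe, and the spectrum of light returned by the tissue
carries the signatures of scattering (a smooth, wavelength-dependent decay)
and of hemoglobin absorption (the Soret band near 410 nm and the Q-bands near
540 and 580 nm). `drspectra` implements a complete, testable analysis chain
for this setting: reflectance calibration, spectral windowing,
standardization, principal component analysis (PCA) with a rank-based
selection of discriminative components, linear discriminant analysis (LDA)
posteriors, specimen-grouped leave-one-out cross-validation (LOOCV), and
pairwise ROC evaluation with Youden-optimal cutpoints.

Because no measured dataset ships with the package, a hierarchical synthetic
generator reproduces the acquisition design and the qualitative structure of
such measurements; every downstream stage is exercised against it.

## Reflectance calibration

Raw detector counts `S_Rd(lambda)` are converted to percent diffuse
reflectance against a lamp reference `S_R(lambda)` (recorded on a
near-perfect diffuse reflectance standard) and a dark/background signal
`S_D(lambda)`:

    R_d(lambda) = (S_Rd - S_D) / (S_R - S_D) * 100

The formula is invariant under any shared affine re-gauging of the three
signals, an identity the tests verify numerically. Wavelengths where
`|S_R - S_D|` falls below `1e-9 * max(S_R)` would blow up the quotient, so
`compute_reflectance()` refuses them with a `degenerate-reference` error
listing the offending wavelengths rather than emitting infinities. Grids must
match exactly; the package never interpolates implicitly.

Spectra beyond 650 nm are discarded: detector noise rises steeply in the
near-infrared (the generator reproduces this), and the informative hemoglobin
features lie in the visible window. `crop_spectra()` restricts to
350–650 nm and, by default, places spectra on a canonical uniform grid of
1150 points spanning the window inclusive (spacing 300/1149 ≈ 0.261 nm).
Resampling is plain linear interpolation — it preserves affine spectra
exactly and is idempotent because grid points shared with the input are
copied, not interpolated. For data already acquired on the canonical grid,
`resample = FALSE` reproduces pure cropping. All wavelength grids in the
package are expressed at 4-decimal precision (the precision of the column
names in the on-disk format), which makes grids exact across file
round-trips.

## Standardization, PCA, and component selection

Reflectance values are standardized wavelength-by-wavelength to mean 0 and
standard deviation 1 (sample sd, `n - 1` denominator). In cross-validation
the standardizer is fitted on the training fold only and applied to the
held-out fold — fitting it on all data would leak the held-out specimen's
distribution into training. Constant columns (sd below `1e-12`) carry no
information; their sd is set to 1 (so z = 0) with a logged warning.

PCA is computed from the centered data matrix, via the `p x p` covariance
eigen-decomposition when observations outnumber wavelengths and via SVD of
the data matrix otherwise; the retained rank is `min(n - 1, p)`, optionally
capped by `max_pcs`. Each loading column's largest-magnitude element is made
positive, a deterministic sign convention that makes results reproducible
across linear-algebra backends.

Components are then ranked for discriminative power: for every pair of
tissues, each component's scores are compared between the two classes with a
two-sided Mann-Whitney U-test (midranks; exact enumeration when the pooled
sample is tie-free with at most 10 values, otherwise the tie- and
continuity-corrected normal approximation). Per pair, the three components
with the lowest p-values are picked — ties break toward the lower component
index, preferring the higher-variance, more stable component — and the
selection is the union over pairs. With four classes (six pairs) the
selection therefore has between 3 and 18 members, a bound the tests assert on
randomized inputs. No multiplicity correction is applied: selection is by
rank, not by threshold.

Cross-validation supports three protocols. `adaptive` re-selects components
in every fold. `fixed` uses a user-supplied component list throughout.
The default `two_pass` first runs an adaptive pass, intersects the per-fold
selections (`consensus_pcs()`), and re-runs with that fixed consensus —
the protocol appropriate for a practical classifier, where per-sample
adaptivity is unavailable. An empty intersection is an error by default;
with `fallback_consensus = TRUE` the components selected in at least half of
the folds are used instead, with a prominent warning. On structured data the
consensus is non-empty; the fallback exists for degenerate (e.g. null)
inputs.

## LDA posteriors

Classification uses the generative view of LDA: class-conditional Gaussians
with a shared covariance, i.e. the rule that maximizes between-class relative
to within-class variance. `fit_lda()` estimates class means and the pooled
within-class covariance (`n - c` denominator) and adds a relative ridge
`1e-8 * trace(Sigma)/k` to the diagonal; selected-PC scores are
near-orthogonal, so the ridge only guards degenerate folds. Posteriors are
computed in log space (no overflow for extreme scores) and returned as
probabilities rather than hard labels, so that ROC analysis can sweep
thresholds downstream.

Priors are configurable. `fit_lda()` alone defaults to empirical class
frequencies. Inside `run_loocv()` the default is **equal** priors, for a
reason worth spelling out: holding out one specimen removes 1/12 of its
class from training, so per-fold empirical frequencies are slightly tilted
against the held-out class — every held-out observation then starts with a
systematic log-odds handicap for its own true class. Under informative data
this is negligible, but under a null (no class differences) it produces
markedly below-chance cross-validated AUC. With the balanced acquisition
design the population priors are equal by construction, so equal priors are
both the faithful and the calibrated choice. This hold-out-induced
below-chance bias of leave-one-cluster-out validation is a known phenomenon
of cross-validation with small fold counts; a residual (the noisier mean of
the smaller training class sits farther from the origin in overfit
directions) remains even with equal priors, which is why null-calibration
checks must average over simulation replicates (below).

## Grouped cross-validation and ROC evaluation

The acquisition design measures each physical tissue sample (specimen) many
times: 6 spots, 30 repeat spectra per spot. Repeated measurements of one
specimen are far more alike than measurements of different specimens, so
an observation-level split would place near-copies of test spectra in
training and inflate performance. `specimen_folds()` therefore builds one
fold per specimen — 48 folds for the full four-tissue design — and the
no-leakage property (the test specimen never appears in training) is
asserted both in code and in tests. The package retains an
observation-level mode (`grouping = "observation"`) purely to demonstrate
this optimism, which the test suite quantifies under inflated specimen
variability.

Cross-validated posteriors are evaluated pairwise. For a tissue pair the
score is the renormalized two-class posterior
`p(pos) / (p(pos) + p(neg))` — invariant to probability mass on the other
classes and equal to the raw posterior in a two-class problem. The ROC curve
sweeps the distinct score values (`score >= threshold` predicts positive);
the AUC is the trapezoidal area, which equals the concordance probability
with ties counted one half (a property the tests verify against a pair-
counting oracle). The reported operating point maximizes the Youden index
`J = sensitivity + specificity - 1`; among tied maximizers the
higher-specificity threshold is reported. The pairwise report is oriented
as in the usual lower-triangular layout: the row tissue is the positive
class against the column tissue.

## The synthetic generator

The generator emulates the stated acquisition design — by default 4 tissue
types x 12 specimens x 6 spots x 30 repeats = 8640 spectra — with a
three-level hierarchy:

* **Tissue optics.** Noiseless reflectance is
  `100 * clamp(specimen * (lipid + baseline * (lambda/500)^-b) *
  exp(-spot * blood * eps(lambda)), 0, 1)`. The pseudo-extinction curve
  `eps` is an analytic stand-in for hemoglobin: three Gaussian bands at
  410/540/580 nm (widths 18/12/12 nm; relative heights 1.0/0.25/0.22 at
  oxygenation 0.5, with the 540/580 balance shifting linearly in the
  oxygenation parameter; amplitude 5 optical-density units at the Soret peak
  for `blood_fraction = 1`). A tabulated hemoglobin spectrum would add a
  data dependency without changing what the pipeline can be tested on.
* **Specimen and spot effects.** Multiplicative log-normal albedo factors,
  `sigma_specimen = 0.10` and `sigma_spot = 0.05` by default — invented
  configuration representing inter-animal and within-sample variation,
  chosen once as plausible magnitudes (10% and 5% albedo scatter).
* **Instrument.** A smooth lamp continuum plus narrow Gaussian emission
  lines (five in 450–495 nm, three in 820–900 nm — invented stand-ins for
  a pulsed xenon lamp's line structure), a constant dark offset of 400
  counts, and Gaussian detector noise with a 25-count floor growing by
  0.8 counts/nm beyond 650 nm, which reproduces the poor near-infrared
  signal-to-noise that motivates cropping.

The default wavelength grid uses spacing 300/1149 nm anchored so that 350
and 650 nm are grid points: exactly 1150 points fall in the retained window,
and the grid extends at the same spacing to roughly 200–900 nm (2681
points). One master seed drives deterministic per-(tissue, specimen, spot)
sub-streams, so identical configurations are bitwise reproducible and
enlarging `repeats_per_spot` only appends draws.

Three scenarios ship with the package. `paperlike` gives the four tissues
qualitatively realistic contrasts: cancellous bone is hemoglobin-dominated
(the largest `blood_fraction`), nerve and salivary gland share a similar
lipid offset, and cortical bone is deliberately an amplitude-scaled copy of
the nerve optics — the two differ only through overall albedo, which is
confounded with specimen-level variation, making the cortical-bone pairs the
hard comparisons and cancellous-vs-gland the easy one. These parameters are
invented calibration tuned only to reproduce that qualitative ordering; they
are not measured optical properties. `separable` spaces the four models
widely apart, and `null` gives all four labels one identical model.

What the generator does **not** emulate: radiative transfer or probe
geometry, fluorescence, wavelength-dependent specimen effects (the albedo
factors are flat across wavelength), drift between acquisition sessions, and
non-Gaussian detector artifacts. Passing tests therefore show that the
statistical chain behaves correctly under a faithful rendering of the
acquisition design's variance structure — not that any particular
performance level would be attained on measured tissue.

## Problem sizes and calibration checks

The test suite runs the full 8640-spectrum design only for count and
preprocessing checks. Cross-validation properties are checked at reduced
design sizes chosen to preserve the design's structure — notably all 48
specimens (12 per tissue, the quantity that limits statistical resolution)
with 2 spots x 3 repeats — because the specimen count, not the repeat count,
governs the behaviour of grouped cross-validation.

Under the `null` scenario the pairwise cross-validated AUC of a single
simulated dataset is itself a random variable whose spread is set by the 12
specimens per tissue (standard deviation on the order of 0.15, whatever the
number of repeats); a single replicate therefore cannot certify calibration.
The calibration check is a Monte-Carlo estimate: the per-pair AUC averaged
over 12 simulation seeds (standard error ≈ 0.15/sqrt(12) ≈ 0.04) is required
to lie in [0.40, 0.60] for every pair. The `separable` scenario must reach
AUC ≥ 0.99 for every pair in a single replicate, and the `paperlike`
scenario must reproduce the difficulty ordering described above.

## Known limitations

* The generator's tissue parameters are qualitative calibration, not
  measurements; absolute AUC values on synthetic data say nothing about
  measured tissue.
* The Mann-Whitney selection inherits the pseudo-replication of repeated
  measurements: p-values computed on spot/repeat-level scores overstate
  evidence for specimen-level contrasts. The pipeline uses them only to
  *rank* components, matching the method it implements, but the p-values
  themselves should not be interpreted inferentially.
* Leave-one-specimen-out estimates retain a small below-chance bias under
  weak signal even with equal priors (see above); comparisons between
  protocols should average over replicates.
* `fixed`-mode component indices refer to each fold's own PCA basis; with
  very small folds the same index can describe different directions across
  folds. The two-pass consensus mitigates but does not remove this.
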