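---
title: "Methods: breath-spectrum classification with stacked sparse autoencoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath-spectrum classification with stacked sparse autoencoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathsae)
```

## The problem and the model

Exhaled breath carries hundreds of volatile organic compounds whose
concentrations shift with disease-state metabolism. Raman-type spectra of
breath samples therefore carry class information in the heights of a modest
number of vibrational bands, buried under baseline drift, detector noise and
occasional cosmic-ray spikes. `breathsae` implements a complete
computer-aided-diagnosis pipeline that separates three groups — early
gastric cancer (EGC, code 0), advanced gastric cancer (AGC, code 1) and
healthy controls (HEALTHY, code 2) — from such spectra.

The classifier is a two-layer *stacked sparse autoencoder* with a softmax
head. A single sparse autoencoder maps an input $x \in [0,1]^d$ through

$$z = f(x) = \sigma(Wx + b), \qquad \hat x = g(z) = \sigma(W'z + b'),$$

with logistic $\sigma$, and is trained by full-batch gradient descent on

$$J(W,b) \;=\; \frac{1}{n}\sum_{i=1}^{n} \tfrac12\lVert x^{(i)} - \hat
x^{(i)}\rVert^2 \;+\; \alpha \sum_{j=1}^{h} \mathrm{KL}\!\left(p \,\Vert\,
\hat\rho_j\right) \;+\; \beta\,\lVert W\rVert_2^2,$$

where $\hat\rho_j$ is the mean activation of hidden unit $j$ over the batch,
$\mathrm{KL}(p\Vert\rho) = p\log\frac{p}{\rho} +
(1-p)\log\frac{1-p}{1-\rho}$ is the Bernoulli Kullback–Leibler divergence
(natural logarithm), and $\lVert W\rVert_2^2$ sums the squared entries of
the encoder and decoder weight matrices (biases excluded). Defaults follow
the study configuration: sparsity target $p = 0.05$, sparsity weight
$\alpha = 4$, learning rate $0.001$, 1000 epochs. Layers are pretrained
greedily and unsupervised — the second autoencoder trains on the first
one's codes — then a three-class softmax is fitted on the deepest codes and
the assembled encoder + softmax network is fine-tuned jointly on the
labeled training data by backpropagating the multiclass cross-entropy
(decoders are discarded at this point, the standard choice).

## Interpretation choices in the objective

Three aspects of the objective were genuinely open and are fixed here as
package policy:

* the KL sum runs over the hidden units of the layer currently being
  trained — the only reading consistent with the definition of
  $\hat\rho_j$ as a per-unit mean;
* the KL term carries the explicit coefficient $\alpha$ (default 4, the
  "sparsity regularization" of the study's parameter table); the
  reconstruction loss is the average of $\tfrac12\lVert\cdot\rVert^2$;
* decoder weights are untied from encoder weights, since the model is
  written with distinct $W$ and $W'$.

Weight initialization is Glorot-style uniform over
$\pm\sqrt{6/(d+h)}$ from a seed; nothing about initialization was
prescribed, and this is the standard choice for logistic units. The default
architecture is hidden sizes $[100, 40]$, the best-performing configuration
of the study's comparison table; the prose alternative (second layer 50) is
one `layer_sizes = c(100, 50)` away.

The softmax and fine-tuning stages use larger default learning rates (0.5
and 0.1) than the autoencoders: both optimize cross-entropy over
[0,1]-bounded inputs, where plain gradient descent at 0.001 would need far
more than $10^3$ epochs to approach its optimum; the autoencoder stages
keep the study's 0.001.

## The synthetic cohort

The study's breath spectra are not publicly deposited, so the package
ships a first-class generator that emulates the *structure* the
preprocessing section describes, at the stated cohort scale: 55 EGC, 89
AGC and 56 healthy samples (200 total), 1200 points per spectrum on a
400–1500 axis. Each spectrum is

* a sum of twelve Gaussian (optionally Lorentzian) bands at class-shared
  centers whose amplitudes are drawn per sample
  (`default_band_library()`): four disease-elevated bands rise
  progressively healthy → EGC → AGC by 0.4 per step, one band is
  suppressed in cancer, and two rise only in advanced disease, with
  between-subject amplitude spread 0.08 — gaps of 0.3–0.4 against a
  spread of 0.08 model clearly class-separated VOC concentrations;
* plus a random degree-2 polynomial baseline (scale 0.4), i.i.d. Gaussian
  noise (sd 0.02 against band amplitudes near 1), and a Poisson(0.5)
  number of narrow positive spikes, triangular, at most 3 points wide,
  2–5× the strongest band — much narrower than the narrowest band FWHM
  (~23 points), which the configuration validator enforces.

On the axis units: the study states the spectral region as 400–1500 "nm"
yet shifts by "2 cm⁻¹" during augmentation; the two are incommensurable,
so the package treats the axis as an ordered unitless coordinate named in
cm⁻¹ by convention and claims no physical calibration.

What the generator does **not** model: instrument response functions,
wavelength-dependent noise, peak-position jitter between subjects,
correlated (pink) noise, or any true VOC chemistry. Passing tests on this
cohort therefore demonstrate that the pipeline recovers class structure of
the kind described — not clinical performance on real breath data, whose
headline accuracies cannot be reproduced without the undisclosed dataset.

## Preprocessing

The chain is spike removal → median filter → baseline correction →
Savitzky–Golay smoothing, each stage optional. The study names the steps
but not the algorithms (its baseline/smoothing lived in proprietary
software), so:

* **Despiking** uses the modified z-score ($0.6745\,(d -
  \mathrm{med})/\mathrm{MAD}$) of the first differences: a spike is a
  sharp rise followed within `spike_width_max` (default 3) points by a
  sharp fall, with the jump also exceeding 5% of the signal range —
  the magnitude gate keeps the infinitesimal curvature step at a smooth
  band apex from being clipped on noiseless data. Flagged points are
  rebuilt by linear interpolation and the pass iterates to a fixpoint,
  making the operation idempotent. Threshold default 6.
* **Median filter**: window 5, reflection padding (all edge handling in
  the package is reflection, stated once here).
* **Baseline**: asymmetric least squares (λ = 1e5, p = 0.01, second-
  difference penalty, iteratively reweighted) by default; an iteratively
  reweighted polynomial fit (degree 3) is the alternative. Both leave
  band heights above baseline intact to within ~5%.
* **Smoothing**: Savitzky–Golay, window 7, order 2 — polynomials up to
  the order pass through unchanged.

The stage order is fixed as listed; the study implies but never states an
order, and despiking before median filtering keeps broad spikes from
bleeding into the rank statistics.

## Augmentation and features

Each preprocessed spectrum is cropped to its centered 1200 points (which
1200 of a longer spectrum are kept was unstated; centering is symmetric
and deterministic) and a copy shifted right by 2 axis units is added with
the same label, doubling 200 samples to 400. The study reports 368
augmented samples and 453,600 values, which does not follow from its
stated crop-and-shift procedure (400 samples × 1200 = 480,000; even 368 ×
1200 ≠ 453,600); the package implements the stated rule and documents the
discrepancy rather than reverse-engineering an unreported step.

Feature extraction detects local maxima, ranks them by topographic
prominence (floor: half the intensity standard deviation; prominence
rather than raw height suppresses shoulder artifacts), keeps the top 50
(ties to the smaller position), re-orders them by position and uses the
**peak heights** as the 50-dimensional input vector — the study says only
that "fifty peaks" feed the network, and height is the attribute that
carries concentration information; width and area stay on the `Peak`
records for diagnostics. Fewer than 50 peaks are padded with flagged
zero-height placeholders. Features are min–max scaled to [0,1] with
statistics fitted on the training partition only (the decoder is a
logistic sigmoid, so inputs must be representable in (0,1)); the
statistics are stored in the model checkpoint and reused verbatim at
prediction time.

## Splitting and evaluation

The default split is 70/15/15 (train/validation/test), the protocol of
the study's results section; its patients section states 75/25, which is
available as `split_spec(c(0.75, 0.25, 0))` — the package keeps both and
does not resolve the conflict. Sizes follow floor(n·fraction) with
remainders assigned train-first; stratified allocation uses controlled
rounding so per-class proportions hold within one sample while the global
partition sizes stay exact. Augmented copies always land in the partition
of their source sample (leakage guard).

Metrics follow the standard one-vs-rest collapse: per class, precision
TP/(TP+FP), recall TP/(TP+FN), F = 2PR/(P+R); overall accuracy is
trace/total of the 3×3 confusion matrix (the study's binary accuracy
formula is exposed per class via `binary_counts()`). A 0/0 rate is
reported as an explicit undefined marker with a `defined` flag — never a
silent zero. Aggregates are macro-averages over classes with defined
values; the study never states its averaging convention, and macro
averaging is the conservative choice for the unbalanced cohort. ROC
curves are one-vs-rest threshold sweeps; AUC is trapezoidal, which equals
Mann–Whitney concordance with ties counted ½ (tested against brute-force
pair counting); the study reports a single AUC per model without defining
the multiclass reduction, so the package reports per-class AUC plus their
macro average.

## Numerical choices and degenerate inputs

* KL arguments are clamped to [1e-8, 1 − 1e-8]; softmax probabilities are
  computed with the max-shift trick and floored at 1e-300 inside logs.
* Argmax ties in prediction break towards the lowest class code.
* Duplicate axis values are a hard error naming the offending value;
  descending files are sorted on load; I/O round-trips at full double
  precision.
* Non-finite training cost aborts with a diagnostic rather than
  propagating NaNs.
* A constant feature column scales to 0 with a warning (placeholder
  columns make this routine, not exceptional).

## Problem sizes used in the shipped checks

Unit and property tests run on reduced instances (cohorts of 18–45
spectra, 250–600 points, tens to hundreds of epochs) chosen so each
property is already decisive at that scale; the end-to-end check runs the
full default cohort (200 → 400 samples, 1200 points, [100, 40], 1000/2000
epoch schedules), which completes in well under a minute on one CPU. The
Monte-Carlo spike-rate check uses 2000 replicates, where the 3-standard-
error band is ±0.15 around the target rate of 5.

## Known limitations

* Synthetic spectra share band *positions* across samples; real breath
  spectra jitter in position, which would stress the position-ordered
  feature alignment. A warped-axis generator would be the natural
  extension.
* Plain full-batch gradient descent is faithful to the study but slow on
  larger cohorts; momentum/Adam are deliberately out of scope.
* The pipeline reports no uncertainty on its metrics; resampling the
  cohort seed is the supported way to gauge run-to-run spread.
* Real-data accuracies quoted in the source study are not reproducible
  here (data available only on request) and are not targets of this
  package's checks.
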