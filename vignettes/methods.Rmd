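---
title: "Enhancer prediction with stacked RBMs: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancer prediction with stacked RBMs: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Enhancers are distal cis-regulatory DNA elements that up-regulate target
genes independent of orientation and distance, which makes them hard to
locate by proximity rules. They do, however, leave footprints: characteristic
histone-modification marks (e.g. H3K4me1), locally depressed DNA
methylation, and biased sequence composition, including elevated GC content.
`epideep` treats enhancer prediction as binary classification of candidate
genomic regions from exactly these three kinds of evidence, using a deep
belief network (DBN) classifier.

## Featurization

Each candidate region is mapped to a fixed-length vector with four column
families, in a frozen order:

* **k-mer composition (168 columns).** For k = 2, 3, 4, all 4^k words are
  collapsed into 4^k/2 groups, because a double-stranded fragment is read
  equally from either strand: a word and its reverse complement are one
  feature. Palindromic words are their own reverse complement; to keep the
  group count at exactly 4^k/2 (8 + 32 + 128 = 168) they are paired with
  each other in lexicographic order. The pairing of, say, `AT` with `CG` is
  arbitrary, but it is deterministic, documented, and preserves the intended
  dimensionality — the alternative (true reverse-complement equivalence
  classes) would give 10, 32 and 136 groups and a different input width.
  Each group's value is the *proportion* of clean length-k windows in the
  region matching either member, not the raw count: proportions make regions
  of different lengths comparable, and windows containing an ambiguous base
  (N) are dropped from numerator and denominator alike. Per k, the values
  sum to 1 whenever at least one clean window exists.
* **GC content (1 column).** (#G + #C) / #unambiguous bases.
* **Methylation (1 column).** The per-base sum of a piecewise-constant
  methylation signal track over the region (value × overlap length), read
  literally as the total amount of methylation in the region.
* **Histone marks (one column per track).** The same per-base sum, one
  column per mark, in the caller-supplied track order. With the classical
  106 marks the full vector has 276 dimensions.

All coordinates are BED-style 0-based half-open throughout, matching the
BED/bedGraph interchange formats, and features are computed on the forward
strand — the reverse-complement collapsing is what makes the k-mer columns
strand-neutral.

Signal sums and GC are unbounded or on very different scales, while the
RBM below models visible units in [0, 1]; features are therefore min–max
scaled per column before entering the network. The scaler is always fitted
on training rows only and applied (with clipping to [0, 1]) to held-out
rows, so cross-validation never leaks test-fold statistics; constant
columns map to 0.

## The model

The classifier is a feed-forward sigmoid network initialized by
unsupervised pretraining. The building block is the restricted Boltzmann
machine (RBM): visible units v, hidden units h, energy

$$E(v, h) = -v^\top W h - b^\top v - a^\top h,$$

joint distribution \(P(v,h) = e^{-E(v,h)}/Z\), and factorial conditionals
\(P(h_j = 1 \mid v) = \sigma(\textstyle\sum_i W_{ij} v_i + a_j)\) and
\(P(v_i = 1 \mid h) = \sigma(\textstyle\sum_j W_{ij} h_j + b_i)\).
Here `a` is the hidden bias and `b` the visible bias, the convention the
conditionals force; real-valued inputs in [0, 1] are fed to the visible
units directly as Bernoulli probabilities.

RBMs are trained by CD-1 contrastive divergence: the positive phase uses
hidden *probabilities* given the data; the negative phase takes one Gibbs
round with sampled hidden states and mean-field visible reconstructions.
Using probabilities where the algorithm permits reduces gradient variance
without changing the fixed points. Updates apply momentum and L2 weight
decay (on W only). Defaults — learning rate 0.1, 50 epochs, batches of 32,
momentum 0.5, decay 1e-4, weights initialized N(0, 0.01²), biases zero —
are standard small-RBM practice and are all exposed in `rbm_config()`.

The DBN is pretrained greedily: the first RBM on the scaled features, each
subsequent RBM on the hidden activation probabilities of the one below.
The canonical architecture on 276 inputs is 276-50-50-200. A single
sigmoid output unit is then attached and the whole network — not just the
output layer — is fine-tuned by backpropagation on binary cross-entropy
with mini-batch gradient descent. A single sigmoid unit with cross-entropy
is mathematically equivalent to a 2-unit softmax for binary labels and is
the simplest faithful realization of a DBN-plus-output-layer classifier.
Prediction is a deterministic forward pass; a region is called positive
when its probability is ≥ the threshold (the boundary counts as positive,
a documented convention).

### Fine-tuning learning rate

The fine-tuning default is learning rate 0.5, epochs 200, batches of 32,
no early stopping (`finetune_config()`). The learning rate deserves a
note: with four stacked sigmoid layers and pretrained weights of small
magnitude, gradients reaching the lower layers are strongly attenuated. At
rate 0.1 the network can sit on the initial plateau (all outputs near 0.5)
for hundreds of epochs when only a few input columns carry signal; at 0.5
the same network exits the plateau and drives training loss below 0.01
within 100 epochs on the synthetic tasks in this package. Since the output
unit and loss keep all gradients O(1) at the top, 0.5 remains stable in
every configuration we ship.

## Evaluation protocol

`make_folds()` builds stratified k-fold assignments: members of each class
are shuffled under the seed and dealt out in a global round-robin, so fold
sizes differ by at most one overall and per class. With the canonical
balanced design of 741 positives and 741 matched negatives (1482 samples,
10 folds), eight folds hold 148 regions and two hold 149; training on the
complement of a floor-size fold uses 1334 samples. (148 × 10 = 1480 ≠ 1482:
a perfectly even split does not exist, and the widely quoted 1334/148
arithmetic corresponds to the floor-size folds.)

`cross_validate()` refits everything per fold — scaler, pretraining,
fine-tuning — with a fold-derived seed, so trials are independent and the
whole procedure is reproducible. The headline number is the mean held-out
error rate over folds; ROC points and AUC (Wilcoxon rank statistic,
midrank tie handling) are computed on the pooled held-out probabilities.

`ablation_suite()` re-runs cross-validation on four nested feature
combinations — histone + k-mer sequence, plus GC, plus methylation, plus
both — on identical folds, mirroring the classical feature-combination
protocol for this problem.

## The synthetic-data generator

Real enhancer studies rest on genome-scale downloads (validated enhancer
coordinates, reference sequence, epigenome tracks) that a test suite
cannot assume. `simulate_dataset()` generates the full study shape
instead:

* i.i.d. random chromosomes at background GC 0.41 (roughly the human
  genome-wide value);
* planted enhancer regions — by default 500 regions, Gaussian lengths
  1500 ± 300 bp (min 500), the length scale of validated distal enhancers —
  whose bases are re-sampled at background GC + 0.10, the direction
  reported for experimentally validated heart enhancers;
* binned signal tracks (25 bp bins, log-normal noise, σ_log = 0.5,
  mimicking binned coverage): by default 10 histone marks multiplied by 4
  inside enhancers, and one methylation track multiplied by 0.25 inside
  enhancers (low methylation marks active regulatory DNA);
* matched negatives: for each positive, a background region of the *same
  length* on the *same chromosome*, placed uniformly, rejecting overlaps —
  the matched-background construction used when curated negatives are
  unreliable.

Defaults are chosen once as a realistic reduced-scale study and are not
tuned to any test outcome. What the generator does **not** emulate:
mappability artifacts, nucleosome positioning, motif grammar, correlated
marks, chromosome-scale covariates, read-level noise. Passing the
synthetic recovery checks therefore demonstrates that the pipeline wiring,
training dynamics and evaluation logic are sound — not that the method
attains any particular accuracy on real epigenomes.

Two derived configurations are used in the package's end-to-end checks,
fixed a priori:

* a **null configuration** (enrichment fold 1, depletion factor 1, GC
  shift 0) under which held-out accuracy must collapse to chance; and
* an **ablation configuration** (histone fold 1, GC shift 0.02,
  methylation depletion 0.25) for the feature-combination comparison. The
  small GC shift matters: a large shift is absorbed almost entirely by the
  k-mer columns, which sit in the baseline combination, making every
  combination tie at zero error. With weak sequence signal and strong
  methylation signal the added families genuinely help, so the comparison
  is informative rather than trivially tied.

## Numerical and engineering choices

* **Exact oracles.** For models with ≤ 20 total units the package can
  enumerate all 2^(n_v+n_h) configurations: `rbm_partition_function()`,
  `rbm_joint_probability()` and an exact mean log-likelihood. These are
  test instruments — the tests verify normalization to 1e-10, conditionals
  against enumeration to 1e-10, positive alignment of the CD-1 gradient
  with the exact gradient, and likelihood ascent during training — and are
  refused for larger models rather than silently approximated.
* **Determinism.** Every stochastic entry point takes a seed and runs
  under a save/restore RNG discipline; per-layer and per-fold seeds are
  derived arithmetically from the master seed. Identical seeds give
  bit-identical models, predictions and output files.
* **Degenerate inputs.** Sequences shorter than k or all-N give all-zero
  k-mer rows with a warning; regions on chromosomes missing from a signal
  track aggregate to 0 with a warning; empty training data, shape
  mismatches, non-binary labels, unscaled RBM inputs and single-class AUC
  are hard errors.
* **Problem sizes.** The shipped end-to-end checks run the full
  architecture (input-50-50-200) with 10 CD epochs and 100 BP epochs on
  1000 regions with 10 marks — sizes at which training has plateaued on
  these tasks while the whole suite stays fast; both are package choices
  exposed through the config objects.
* **Serialization.** Models round-trip through a versioned JSON container
  (arrays at full precision, plus the feature-name list and fitted scaler),
  and feature matrices through CSV with an id index and label column, so
  runs are interchangeable across sessions.

## Limitations

* Bernoulli visible units with [0, 1]-scaled inputs are a pragmatic choice;
  Gaussian visible units are a known alternative for continuous data and
  are out of scope here.
* CD-1 is a biased gradient estimator; the package asserts directional
  agreement with the exact gradient on tiny models, not convergence to the
  maximum-likelihood solution.
* The min–max scaler is sensitive to outliers in the training fold;
  clipping bounds the effect on held-out data but a heavy-tailed signal
  column can still compress most of its dynamic range.
* Synthetic results do not transfer to real epigenomes (see above); the
  package ships no real genome data.
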