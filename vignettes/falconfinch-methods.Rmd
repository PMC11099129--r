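---
title: "Methods: the falcon finch optimizer and the lesion classification pipeline"
author: "falconfinch package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the falcon finch optimizer and the lesion classification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(falconfinch)
```

## Overview

`falconfinch` implements a hybrid swarm metaheuristic — falcon finch
optimization (FFO) — and embeds it in a two-class skin-lesion
classification pipeline. The optimizer hybridizes sparrow-search
producer/scrounger foraging with Harris-hawk soft/hard besiege moves and a
perching stage that pulls individuals toward the best-known position. The
pipeline runs: non-local-means denoising, standardization to
224 x 224 x 3, extraction of eight statistical features plus a pluggable
deep-feature backbone (109 values in total), a small convolutional
classifier on a 22 x 11 input plane, FFO tuning of the output layer, and
k-fold / training-percentage evaluation reporting accuracy, sensitivity and
specificity. A seeded synthetic generator of dermoscopy-like images makes
every stage testable offline.

## The optimizer

FFO minimizes `f : R^s -> R` over a box `[Z_lb, Z_ub]` with a population of
`l` individuals over `iterMax` iterations. Individuals are kept sorted by
fitness; the best `producerFraction * l` (default 0.2) act as producers.
Each iteration applies four stages, with greedy acceptance after each (an
individual keeps its old position when the candidate is worse) and
componentwise clipping to the box:

1. **Foraging (producers).** In the safe regime (alarm draw `T` below the
   safety threshold `P_alarm = 0.5`) each coordinate contracts as
   `Y_i <- Y_i exp(-i / (beta * iterMax))`, `i = 1..s` the dimension index
   and `beta ~ U(0, 1]`. In the alarmed regime the position is multiplied
   by one standard-normal draw broadcast over dimensions. The multiplicative
   form is the printed recursion of the source method; the additive
   sparrow-search original (`Y + N`) is available behind the `ssaCompat`
   flag. Note the contraction drives coordinates toward zero, so the
   method carries an origin bias on objectives whose optimum is at the
   origin (sphere, Rastrigin); this is a property of the published
   dynamics, not of this implementation.
2. **Accumulation (scroungers).** The worse half
   (`rank > l/2`, the "starving" scroungers) jump to
   `N * exp((Y_worst - Y) / rank^2)`; the better half move to
   `Y_opt + sum_j(|Y_j - Y_opt,j| * B+_j)` where `B` is a random +/-1 row
   and `B+ = t(B) (B t(B))^-1` its pseudo-inverse (entries `B_j / s`).
3. **Besiege (escalation).** When `T >= 0.5` a scrounger escalates: with
   selector `z >= 0.5` the soft besiege mixes the starving kernel, the pull
   toward the best scrounger and the pull away from the optimum with
   constants `x1 = x2 = x3 = 1/3`; with `z < 0.5` the hard besiege averages
   the best scrounger, the individual, an escape-energy term
   `E = 2 E0 (1 - k / iterMax)` (`E0 ~ U(-1, 1)`) and a normalized distance
   to the worst individual. Each mode has a rapid-dive companion move;
   since the source defines no dive trigger, the dive replaces the base
   move only when its fitness is better (greedy).
4. **Perching.** Every individual (configurable to producers only) blends
   its position with the best-known position ("the falcon"): in the safe
   regime with `p >= 0.5`, `0.5 Y exp(-i/iterMax) + 0.5 Y_fal -
   n1 |Y_fal - 2 n2 Y|`; otherwise `0.5 (Y + N) + 0.5 (Y_prey - Y_avg -
   n3 (Z_lb + n4 (Z_ub - Z_lb)))`. Both the falcon and prey symbols bind to
   the elitist global best; `Y_avg` is the population mean.

**Symbol bindings chosen where the source is silent.** The escape energy
`E`, jump strength `V ~ U(0, 2)`, `Q ~ N(0, 1)` and the fitness
normalizers `S_best`/`S_worst` (bound to the current best/worst fitness)
follow the Harris-hawk conventions and are config-exposed. `Y_scr` binds to
the best scrounger (the first non-producer rank). The hard-besiege branch
condition is `z < 0.5`; as printed, both besiege cases carry the same
condition, which would make the hard besiege unreachable. The scrounger
starvation condition is `rank > l/2` over fitness-sorted individuals (the
printed `fin > s/2` compares an individual index against the dimension,
which is vacuous whenever `s != l`), and the squared denominator is the
fitness rank.

**Determinism.** All stage draws for one individual in one iteration
(`T, z, p, beta, N, n1..n4, E0, V, Q, B`) are consumed in a fixed order at
the start of the iteration, whichever branches later fire. This makes runs
bit-reproducible under `seed` and lets an independent reduced-mode oracle
replicate the stream exactly (the test suite does this for 10 seeds).

**Numerical choices.** Greedy acceptance uses `<=`, so a tie moves; the
elitist best can therefore never worsen, which is the invariant the
convergence history is checked against. Boundary handling is componentwise
clipping. A degenerate best-worst fitness gap in the hard besiege is
floored at 1e-12 in magnitude (sign preserved; enable
`options(falconfinch.verbose = TRUE)` to log occurrences). Iteration stops
after exactly `iterMax` steps — the published procedure has no other
stopping rule — and `iterMax = 0` returns the best of the initial
population.

## Features

The statistical block is computed on the luminance (Rec. 709) of the
standardized image: mean, population standard deviation, sample variance
(divisor `q - 1`), median, skewness (`m3 / sigma^3`), kurtosis
(`m4 / sigma^4`), harmonic mean and geometric mean. Zero pixels are offset
by `1e-8` for the harmonic/geometric means; constant images take skewness
and kurtosis 0 by convention. Several of the printed formulas are
typographically inconsistent (a missing square root, a median index in
place of its value, a single z-score for skewness, a product in place of
the reciprocal sum, a missing q-th root); the standard textbook definitions
are implemented and the printed forms remain available via
`mode = "paper_literal"` for comparison.

The deep-feature slot is a pluggable `Backbone` (deterministic map from a
standardized image to `d` values, default `d = 101` so the concatenated
vector has length 109, matching the published total). Two implementations
ship:

* `descriptorBackbone()` (default): 20 ABCD-style lesion descriptors — the
  radial border-signature Fourier amplitudes (harmonics 1-8 of the
  darkness-weighted boundary radius over 36 angular bins), the signature's
  dispersion, darkness mass, eccentricity and third/fourth moment
  invariants, gradient energy, and darkness-weighted colour means and
  dispersions — plus seeded random Gabor-patch projections of the luminance
  plane filling the remaining dimensions. A 3 x 3 grayscale dilation is
  applied before shape analysis so thin dark hair strokes do not distort
  the darkness-weighted moments. These are the classic pre-deep-learning
  descriptors of lesion asymmetry, border irregularity and colour
  variegation.
* `randomProjectionBackbone()`: a plain seeded Gaussian projection of the
  luminance plane. It is kept as the minimal reference implementation, but
  raw global projections carry almost no lesion-shape information and the
  classifier generalizes poorly on them; this motivated the descriptor
  default.

Non-local-means denoising uses patch 7, search window 21 and strength
`h = 10/255` on the `[0, 1]` scale by default, implemented offset-wise with
integral images (weights `exp(-SSD/(count * h^2))`, border patches clamped
and count-normalized).

## The classifier

The canonical network reconstructs the published parameter table: a
22 x 11 x 1 input plane, three same-padded 3 x 3 ReLU conv blocks (16, 32,
64 filters), each followed by a shape-preserving max-pool (pool 2,
stride 1: the table shows identical shapes before and after pooling),
dropout (rate 0.25; unstated in the source), flatten (width 15,488), a
64-unit ReLU dense layer and a 2-unit softmax head. Per-layer counts are
160 / 4,640 / 18,496 / 991,296 / 130 (1,014,722 in total); the 3 x 3
kernel and single input channel are the only reconstruction consistent
with the printed counts. The table also repeats a conv/flatten/dense block
after the first dense row; this is treated as a typographical duplication
rather than architecture. The 109-feature vector is zero-padded to 242 and
reshaped row-major to 22 x 11 — invented plumbing, since the source never
reconciles the feature dimension with the input plane.

Training minimizes the MSE between the softmax output and one-hot targets
with Adam (learning rate 1e-3, standard moment constants), batch size 32.
The published schedule is 100 epochs; the desk-scale default in the
evaluation harness is 30 epochs, which the loss curves on the synthetic
study show is past convergence for these problem sizes. Gradients are
computed by backpropagation through the exact forward pass (the test suite
validates them against finite differences).

`ffoTune()` flattens the head's 64 x 2 + 2 = 130 parameters into the FFO
decision vector. The activations feeding the head do not depend on those
parameters, so they are cached once and each fitness evaluation is a
single affine map plus softmax. The search box is `w +/- (1 + |w|)` around
the current head `w`, the current head is injected into the initial
population, and write-back is greedy — together these guarantee the tuned
model's tuning-fold MSE never exceeds the input model's. Tuning only the
head is deliberate: a population metaheuristic over all 991k hidden
weights is hopeless, and the source attributes tuning to "this layer"
(the fully connected output). Gradient training and tuning run once each,
in that order.

## The synthetic study conditions

The generator emulates a two-class dermoscopy collection at the reference
class sizes (1800 benign / 1497 malignant; `smallSpec()` is the 60/50
test-scale variant). Each lesion is a radial contour
`R(theta) = r0 * shape(theta) * pert(theta)` on a textured skin background:

* **Asymmetry** `A`: `shape = 1 + A (0.6 cos 2(theta - phi) +
  0.4 cos 3(theta - phi))` — eccentricity plus 3-fold deformation. (A pure
  first-harmonic radial term would only translate the contour, which is
  why asymmetry is carried by harmonics 2-3.) Benign `A ~ U(0.05, 0.15)`,
  malignant `A ~ U(0.35, 0.60)`: disjoint by construction, so thresholding
  the stored parameter at 0.25 classifies 100% >= the documented 95%
  ceiling.
* **Border irregularity**: `pert = 1 + sum_{m=4..7} a_m cos(m theta +
  phi_m)` with the amplitude budget (benign `U(0.02, 0.06)`, malignant
  `U(0.12, 0.30)`) split randomly over the modes.
* **Colour variegation**: malignant lesions carry 2-4 Voronoi colour
  patches jittered +/-0.15 around a common brown; benign a single colour.
* **Nuisance**: background tone (0.80, 0.62, 0.55) with low-frequency
  sinusoidal texture, additive Gaussian noise (sd 0.03), and 1-3 dark
  quadratic-Bezier hair strokes on 20% of images.

Generation is two-phase: `lesionParameters()` draws the labelled parameter
manifest (the ground truth for recovery checks and the dataset-size
contract), `generateLesions()` renders rasters from it deterministically.

**What the generator does not model**: real dermoscopic texture (pigment
networks, globules), illumination gradients, specular highlights, varied
skin tones, or any clinical validity. Passing the pipeline tests shows the
machinery recovers planted, well-margined class structure at small n; it
says nothing about performance on real dermoscopy collections, which is
why the published headline accuracies are outside this package's test
surface.

## Evaluation harness

`runHarness()` extracts features once (they are deterministic per image),
z-scores them on the training partition of each fold, trains the canonical
classifier, tunes the head on an inner stratified 20% carve-out of the
training partition (held out from gradient training; stratification
matters — a single-class tuning fold collapses the head to the majority
class), and predicts the held-out fold. Malignant is the positive class.
Stratified k-fold splitting deals shuffled class indices round-robin, so
every fold's class ratio is within one sample of the global ratio;
unstratified splitting (`labels = NULL`) supports leave-one-out. Metrics
with zero denominators are flagged undefined, never coerced. The k-fold
report aggregates by the unweighted mean across folds, with pooled
confusion counts also available; percentages print to two decimals.

The chance-level null check shuffles labels and evaluates with 5-fold
pooling (110 predictions), so the 50 +/- 10 band is a meaningful binomial
band rather than a coin flip on a 22-sample hold-out.

## Problem sizes and defaults

The desk-scale study uses the 110-image small spec at 224 px, 30 training
epochs, 20 tuning iterations and optimizer budgets of `l = 30`,
`iterMax = 200` on the analytic benchmarks; these sizes are the package's
test conditions and run in a few minutes on one CPU. The full-scale class
sizes and the 100-epoch schedule remain available through
`paperScaleSpec()` and the `epochs` arguments.

## Known limitations

* The optimizer's printed producer recursion contracts toward the origin,
  biasing it on origin-centred objectives; benchmark comparisons in this
  package therefore use random search with a matched evaluation budget as
  the baseline rather than claiming general superiority.
* The hard-besiege dive adds the scalar `(1 + E V)` to a position vector —
  dimensionally odd, but implemented as printed.
* Undefined source symbols were bound by convention (documented above);
  other bindings are defensible and config-exposed where they matter.
* The default backbone is a hand-designed descriptor bank, not a learned
  representation; it stands behind the same interface as a pretrained
  network wrapper but will not transfer to imaging domains whose class
  structure is not morphological.
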