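---
title: "Detecting intracranial haemorrhage with Monte Carlo trained networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intracranial haemorrhage with Monte Carlo trained networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ichtriage)
```

## The problem and the approach

Acute intracranial haemorrhage (ICH) is hyperdense on non-contrast head CT:
fresh blood attenuates around 60--90 HU against brain parenchyma near 35 HU.
A triage system has to answer two questions per case: *is there blood?*
(detection), and if so *what kind?* (EDH/SDH, SAH, or IPH/IVH —
classification). `ichtriage` implements a deliberately minimal pipeline for
both, built around two unconventional choices:

1. **No convolutions.** Each case is reduced to a handful of small square
   grayscale images before any network sees it, so tiny fully-connected
   networks (hundreds of nodes, 1--3 hidden layers) suffice.
2. **No gradients.** Networks are trained by derivative-free random
   optimization: perturb a random subset of weights and biases, keep the
   perturbation only if the average training error over *all* training
   samples strictly decreases. The forward pass is the only network
   computation ever performed.

## Image preparation

Raw HU slices are first brain-windowed (level 40 HU, width 90 HU): the
linear map `g = round(255 * clamp((v - (level - width/2)) / width, 0, 1))`
sends -5 HU to black, 85 HU to white, and blood near the top of the window
where it is maximally conspicuous. Rounding is half-up, the 8-bit display
convention.

The intracranial extent — the contiguous run of slices with cranial content
— is located by counting pixels above a fixed grayscale floor (default
10/255, at least 50 such pixels per slice). The floor is a free parameter;
the windowed skull ring saturates at 255 so any low floor works, and the
synthetic phantoms confirm the located extent matches the generator's
ground truth exactly.

The extent is split into ten deciles of relative intracranial height by
`band(i) = floor(10 * (i - first) / n_extent) + 1`, an exact partition with
band sizes differing by at most one slice (3--4 slices per band for a
typical ~36-slice head). The slices of one band are summed pixelwise and
linearly rescaled so the maximum is 255: summation is the whole
dimensionality reduction — no registration, no segmentation — and the
rescale removes the dependence on band cardinality. The bottom two and top
two deciles carry little haemorrhage and are excluded from experiments.

Each summed image is cropped to the tight bounding box of its content and
stretched *anisotropically* to an S x S square (bilinear interpolation,
aspect ratio deliberately not preserved). This single step normalises head
size, position and much of the tilt across cases; an optional
principal-axis rotation was considered and rejected as the crop-and-fit
already makes the output translation invariant and scale-free. For subtype
classification the average square image of the *training-set* normal cases
of the same band is subtracted (negatives clamped to zero), which removes
the skull ring and shared anatomy and leaves mostly lesion.

Finally the square is reduced to R x R pixels (R between 16 and 80) by
exact area averaging — a box filter, chosen over interpolating filters
because it is deterministic and alias-resistant at 4--25x reduction — and
divided by 255, giving R^2 input values in [0, 1]. Horizontal flipping
doubles the training set; left-right anatomy is near-symmetric, so a
mirrored head is a plausible head.

## The network and its training

The network is a plain dense stack: `activation(W x + b)` per layer,
logistic sigmoid everywhere including the output layer (the activation is
configurable; sigmoid-everywhere is the default because outputs must live
in (0,1) to match the one-hot targets). Detection uses two output nodes
(positive, negative) with targets (1,0)/(0,1) and the scalar detection
value `(output_p - output_n + 1) / 2` feeding the ROC analysis;
classification uses three output nodes with one-hot subtype targets and an
argmax decision (ties to the lowest index, so decisions are deterministic).

Training hyperparameters, all configurable in `train_config()`:

| parameter | default | meaning |
|---|---|---|
| `init_range` | ±0.2 | uniform initialisation of every weight and bias |
| `delta_range` | ±0.1 | uniform perturbation added to each selected variable |
| `attempts_per_event` | 30 | sequential perturbation attempts per drawn subset |
| `ratio_start`, `ratio_end` | 15%, 1.5% | selected fraction of variables, first to last cycle |
| `cycle_budget` | 9.0 | cumulative drawn fraction per cycle (900% of the variable count) |
| `cycles` | 10 | training cycles per session |

A cycle therefore performs `ceil(9.0 / ratio)` selection events (60 at 15%,
600 at 1.5%); each event draws one variable subset without replacement and
makes 30 attempts on it, each attempt giving every selected variable its
own fresh uniform delta, accepted only on a strict decrease of the training
error (mean over samples of the summed squared output-target differences).
Rejected attempts restore the parameters bit-exactly. The error curve
recorded along accepted changes is consequently non-increasing by
construction — this is the algorithm's defining contract and is asserted as
a test invariant — while the score (argmax accuracy) is tracked as a
subsidiary reference and may fluctuate.

Several points the training procedure leaves open were resolved as follows,
each switchable where reasonable: the 30 attempts apply to *one* drawn
subset with greedy immediate acceptance (a keep-best-of-30 variant sits
behind `keep_best = TRUE`); every selected variable gets its *own* delta;
the selection ratio decays *linearly* across cycles (geometric behind
`ratio_schedule`); the 900% budget is accounted *per cycle*; ties in the
error comparison are rejected, preventing drift along flat directions; and
biases are selected from the same pool as weights. All randomness flows
through R's generator in a fixed draw order, so a session is bit
reproducible from its seed.

## Evaluation

Detection values are swept over all unique thresholds (positive when
`value >= cutoff`) and the ROC integrated trapezoidally; this equals the
Mann-Whitney statistic `P(v_pos > v_neg) + 0.5 P(v_pos = v_neg)`, and the
test suite holds the two routes together to 1e-12 on a thousand random
instances. Operating points are reported both at the fixed 0.5 cutoff (at
which the trainer's score equals detection accuracy) and at the Youden
optimum (ties resolved toward sensitivity). Summary accuracy is
prevalence-weighted:
`(n_pos * sens + n_neg * spec) / (n_pos + n_neg)`, which collapses to plain
count accuracy whenever sensitivity and specificity are themselves count
derived. Percentages are carried unrounded and rounded half-up to one
decimal only at report time. The package ships a reference results table
from the clinical experiment this design mirrors;
`reproduce_reference_tables()` recomputes every derived cell (per-band
weighted accuracies, the unweighted Average row, pooled subtype rates) from
the printed counts and rates.

## The phantom generator

Clinical CT cannot be shipped, so the pipeline is exercised on synthetic
head phantoms: per slice an elliptical skull ring (~900 HU) that shrinks
toward the vault, a brain interior at 35 ± 3 HU, air at -1000 HU outside,
and air-only slices padding both ends of the stack so extent location has
something to find. Per-case jitter — global scale 0.85--1.0, tilt ±8°,
centre offset ±5% — emulates the between-patient variation the square
expansion exists to remove. Lesions are drawn at 60--80 HU (hyperdense in
the brain window, as acute blood is) inside a configurable relative-height
band, default 35--55% so the 41--50% decile always contains lesion. The
subtype geometries are coarse archetypes, not radiology: a crescent hugging
the inner skull margin (type 1), thin midline-plus-arc streaks (type 2), a
compact interior blob (type 3).

What the phantoms do *not* model: CT physics (beam hardening, partial
volume, noise correlation), anatomy (ventricles, sulci, grey/white
contrast), and — most importantly — diagnostic difficulty. Phantom lesions
are conspicuous by construction, so a pipeline that reaches AUC ~1.0 on
phantoms has demonstrated only that every stage is wired correctly and that
the trainer can fit a real signal; no claim about clinical performance
follows, and the reference table above is the reminder of what clinical
numbers look like (AUC 0.76--0.90 per band).

## Problem sizes and numerical choices

The default end-to-end experiment (`run_phantom_experiment()`) uses 100
training and 50 validation phantoms at 128 x 128 pixels and 36 slices, the
41--50% band, 20 x 20 input resolution and a 400-40-20-10-2 network (17,092
variables) — sizes chosen so the whole study runs in about a minute on one
core while still exercising the full architecture of interest. The XOR
fixture (2-8-2) is the trainer's convergence regression: one default
session reaches a perfect score from any tested seed. Degenerate inputs are
handled explicitly: empty datasets, all-zero images, single-class ROC
inputs and zero-width windows raise classed errors rather than propagating
NaNs; a zero `delta_range` session accepts nothing and returns its
initialisation.

## Limitations

Training is embarrassingly sequential (each acceptance conditions the
next), so sessions parallelise only across models, not within. The
intracranial-extent heuristic assumes the skull is the brightest structure,
true after brain windowing but not on raw HU stacks. And the
normal-average subtraction assumes enough training normals per band to
average anatomy away; with very few normals the residual keeps skull rim
artefacts.
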