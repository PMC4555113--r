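---
title: "Recognizing food records with a bag of visual words: models and methods"
author: "bowfood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing food records with a bag of visual words: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A photographic food record replaces the pen-and-paper food diary: the user
photographs each meal, and software decides which food categories the
photograph contains.  Two properties make this harder than ordinary
single-label image classification.  First, a meal photograph routinely
contains several foods at once, so the recognizer must emit a *set* of
categories.  Second, realistic training sets are tiny — a handful of
positive photographs per category — which rules out data-hungry methods and
favours a classical bag-of-visual-words (BoW) pipeline with strong,
hand-designed local features.

`bowfood` implements that pipeline end to end: feature extraction over
three complementary channels, chi-squared K-means vector quantization,
one-vs-rest linear SVM scoring, single- and multi-label decision rules,
and a Jaccard-index evaluation protocol in which the multi-label decision
threshold (the *recognition sensitivity*) is swept per category.

## The model

### Features

Images are decoded to 8-bit RGB (`load_image()`) and halved once by area
averaging when either dimension exceeds 2000 px (`maybe_downscale()`) — a
speed rule that also thins the interest-point population on very large
photographs.  Interest points are difference-of-Gaussian scale-space
extrema with sub-pixel refinement, low-contrast rejection, edge-response
rejection, and a dominant gradient orientation
(`detect_interest_points()`).  Three descriptors are computed at every
point, index-aligned across channels:

* **shape** — a 128-dimensional histogram of gradient orientations on a
  4×4 spatial grid with 8 orientation bins, over a patch scaled by the
  point's scale and rotated to its orientation; L2-normalized with the
  standard 0.2 clamp-and-renormalize.
* **texture** — a 59-bin uniform local-binary-pattern histogram, LBP(8,1),
  over a square patch of side `max(16, round(12 * scale))`, L1-normalized.
  The comparison is strict (`neighbour > centre`), so a constant patch maps
  to the all-zeros pattern; the code is invariant to monotone intensity
  shifts, which is the property that makes it robust to illumination.
* **colour** — a joint 4×4×4 histogram with each RGB channel quantized
  into four equal bins, over the same patch, L1-normalized.  The joint
  (64-bin) form preserves channel co-occurrence — a red tomato and a green
  apple of similar brightness stay distinguishable — and is the reading we
  adopt over three concatenated 4-bin marginals.  A whole-image variant
  (`colour_histogram_global()`) is kept for completeness but does not feed
  the default pipeline, because every channel is meant to feed a codebook
  of its own.

All three descriptors are non-negative by construction, which the
chi-squared metric requires.

### Codebooks

Per channel, the descriptors pooled over *all* training images are
clustered into K codewords (defaults K = 100 shape, 40 texture, 50
colour) by K-means under the chi-squared histogram distance

d(u, v) = ½ Σᵢ (uᵢ − vᵢ)² / (uᵢ + vᵢ),

with zero-denominator terms contributing zero (the continuous limit).  We
use one shared codebook per channel rather than per-category codebooks:
this is the standard BoW construction, and it is what makes a single
concatenated histogram (and a single classifier input space) well defined.

Lloyd iterations assign by chi-squared distance and update centroids by
the arithmetic mean.  The mean is not the exact chi-squared barycentre (no
closed form exists), so a mean update is not mathematically guaranteed to
lower the chi-squared objective; `kmeans_chi2()` therefore stops — keeping
the previous state — if an update would raise it, making the recorded
objective trace non-increasing by construction.  Initialization is
k-means++-style seeding under the same metric, fully determined by the
`seed` argument; `nstart` restarts are available in the manner of
`stats::kmeans()`.  Empty clusters are re-seeded with the features
farthest from their centroids.

An image is encoded by assigning each interest point to its best-matching
codeword per channel (ties to the lowest index), counting, L1-normalizing
each channel block, and concatenating `[shape | texture | colour]`
(default length 190).  Per-channel normalization keeps channels with
different codebook sizes and point counts from dominating arbitrarily.
Images with zero interest points are *unencodable*: training skips them
with a warning, prediction flags them, and evaluation counts them as
recognized for no category.

### Classification and decision rules

One soft-margin linear SVM is trained per category (positives = images
whose label set contains it, so multi-label images are positives for every
category they contain).  The margin optimization is delegated to LIBSVM
via `e1071::svm`; each fitted classifier is reduced to explicit weights
and bias, so scoring is a plain dot product.  Because positive sets are
small (4–8 images) against many negatives, the hinge loss is
class-weighted by default with weights proportional to 1/n_class — a
normalization chosen so that duplicating every training example leaves the
objective, and hence the decision boundary, exactly unchanged.  The
regularization strength C defaults to 1 and is exposed.

For an image known to contain a single food, the predicted category is the
argmax of the scores (ties to the first category in the model's order).
For meal images, category *i* is declared present iff its score strictly
exceeds the recognition sensitivity ε — strict inequality, exactly as the
rule is stated.  The predicted set is monotone in ε.

### Evaluation

For category *i*, with M_i the test images truly containing it and
M_i^R(ε) those recognized at sensitivity ε, the accuracy is the Jaccard
index r_i(ε) = |M_i^R(ε) ∩ M_i| / |M_i^R(ε) ∪ M_i|, and the reported
r_i = max over ε of r_i(ε).  Because the recognized set only changes when ε
crosses an observed score, the sweep over the grid
{s − 1e-9 : s a distinct score} ∪ {max score + 1e-9} realizes *every*
achievable recognized set, so the maximum is exact, not approximate; on
ties the smallest maximizing ε is reported.  If both sets are empty we
define r = 1 (nothing to find, nothing claimed) and log the occurrence;
the convention is never exercised by well-formed manifests.  The overall
accuracy is the unweighted mean of the per-category r_i, which is also how
the per-category columns of published food-recognition tables aggregate to
their printed overall rows.  `evaluate_bowfood()` maximizes ε per category
and per feature configuration independently, the reading consistent with
r_i = max over ε.

## The synthetic study profile

The photographic dataset this class of system is evaluated on is not
publicly released, so the package ships a generator
(`generate_dataset()`) that emulates its *structure*: 10 categories,
4–8 single-label positive training images per category, 13–20 test images
owned by each category, and (by default) 30% of test images multi-label
composites of up to five categories, on 128×128 px canvases.  Category
identity is carried by colour, texture and shape signatures
(`category_spec()`), with the defaults chosen once as follows:

* **Base colours** sit at colour-quantization bin centres (32, 96, 160,
  224-ish) so that per-pixel jitter and the mild global illumination
  scaling (0.95–1.05 by default) do not flip item pixels across bin
  edges.  The background grey is 110 — deliberately *off* the 128 bin
  edge, because a background at an edge would flip wholesale between two
  colour bins under illumination scaling and swamp the signal of
  small-coverage categories.
* **Textures** (speckle, stripes, additive blobs, at category-specific
  frequency and contrast) serve two purposes: they are channel signatures,
  and they guarantee interest points on item interiors.  Perfectly smooth
  synthetic surfaces — unlike real food surfaces — yield almost no
  scale-space extrema and make items invisible to a sparse-keypoint
  pipeline, so every default category carries some texture; `"smooth"`
  remains available as a texture type.
* **Multi-label composites** draw 1–4 extra categories with probabilities
  (0.7, 0.2, 0.07, 0.03): most real meal photographs contain two or three
  foods, and items shrink as more are placed so composites fit the canvas.
* The categories `berries_blue`/`berries_green` are identical except for
  base colour: they are the designated probe pair for colour-channel
  ablation, mirroring the role of colour in telling similar-shaped foods
  apart.

Generation is fully reproducible: the same seed yields byte-identical
images and manifest.

What passing on this profile shows — and what it does not.  The synthetic
categories are separable by construction; end-to-end recovery
demonstrates that detection, description, quantization, training, the
decision rules and the sweep compose correctly, and the ablation
demonstrates that the channels carry the intended information.  It does
not certify accuracy on photographs: real food images have clutter,
occlusion, specularity, viewpoint and intra-class variation that the
generator deliberately does not model, and published accuracies on real
data are far below the synthetic ceiling.

## Numerical choices and edge cases

* Detector: 3 scales per octave, base scale 1.6, edge-response ratio 10.
  The DoG contrast threshold defaults to 0.02 (applied as `thr/3`), more
  permissive than the common 0.04, suited to low-contrast food surfaces.
  Images whose smaller dimension is ≤ 512 px start the pyramid one octave
  down (bilinear 2× upsampling) — the standard way to recover fine-scale
  structure on small images.  Refinement moves a candidate at most five
  times; non-converged candidates are dropped.
* Downscaling uses exact 2×2 block averaging (the area-average for a
  factor of two) with floor division on odd dimensions, applied once and
  never iterated.
* K-means: assignment-convergence stop, 300-iteration cap, and the
  objective-descent guard described above.  With a fixed seed the result
  is bit-reproducible.
* SVM: LIBSVM termination tolerance 1e-6; after extraction the sign of
  each linear model is oriented so positives score higher, guarding
  against label-order conventions of the backend.
* Ties: codeword assignment and the argmax rule break ties by lowest
  index; the sensitivity sweep reports the smallest maximizing ε.
* Model archives bundle codebooks, classifiers, configuration and a
  codebook checksum in one file, so classifiers can never be applied to
  histograms encoded against different codebooks; archives round-trip
  bit-exactly.

## Problem sizes used in the shipped checks

The package's own verification runs the full default profile (10
categories, ≈ 60 training and ≈ 165 test images at 128×128) once for the
end-to-end recovery and ablation checks, and smaller 2–4-category profiles
with reduced codebooks for interface, serialization and reproducibility
tests.  Oracle comparisons (distance, assignment, sweep, small-instance
K-means optimality) use brute-force re-implementations on instances small
enough to enumerate.

## Known limitations

* The feature extractor is a faithful but plain-R implementation (with a
  compiled chi-squared kernel); it favours clarity and determinism over
  raw speed, and large photographs cost seconds rather than milliseconds.
* Scores are raw SVM decision values, not calibrated probabilities; the
  per-category ε sweep makes the evaluation invariant to any monotone
  rescaling, but a deployed system would need a held-out calibration to
  pick one operating ε.
* One shared codebook per channel is the implemented reading; per-category
  codebooks are a plausible alternative reading of this family of systems
  but are not implemented.
* No EXIF orientation handling, no fiducial markers, no portion-size
  estimation, no nutrient-database mapping.
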