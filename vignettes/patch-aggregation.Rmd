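---
title: "Cluster aggregation of patch-level cancer calls: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster aggregation of patch-level cancer calls: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchagg)
```

## The model

A whole-slide image is tiled into a lattice of non-overlapping square
patches. A patch classifier assigns each tissue patch a confidence score in
$[0, 1]$; binarizing at a threshold $t$ gives per-patch calls. The package's
central object is the aggregation rule that turns those calls into a slide
and patient diagnosis:

* **Slide.** $D(s) = 1$ iff the binary lattice contains a maximal connected
  component of positive patches with at least $k$ members
  (4-connectivity by default).
* **Patient.** $D(S) = D(s_1) \cup \dots \cup D(s_l)$ over the patient's
  slides.

The statistical rationale: conditional on truth, patch-level classifier
errors are approximately independent across patches, so false positives
scatter, while tumour patches are spatially contiguous. For a lesion-free
slide with $N$ tissue patches and per-patch false positive rate $\alpha$,
the rule at $k = 1$ fails with probability $1 - (1-\alpha)^N$ — near 1 for
realistic $N \approx 5000$ — whereas a $k$-cluster of scattered false
positives requires $k$ errors to land on adjacent cells. Conversely a
compact lesion of $h \ge k$ patches with per-patch sensitivity $s$ is
detected with probability $\ge s^h$ at worst (exactly $s^k$ for an isolated
$k$-patch lesion whose patches must all fire, e.g. $0.95^4 = 0.8145$ for a
$2 \times 2$ lesion at $k = 4$). Both closed forms are verified against the
Monte Carlo machinery in the test suite.

The union rule at patient level multiplies false positive mass —
$\mathrm{FPR}_{patient} = 1 - (1 - \mathrm{FPR}_{slide})^m$ for $m$
independent slides — which is why the slide-level FPR must be driven close
to zero *before* the union, and why the cluster size is the pivotal knob of
the whole pipeline.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `patch_size` | 300 | px | tile side at ×20 magnification (0.5 µm/px); small enough to keep lesion boundaries sharp, large enough for tissue context |
| `input_size` | 299 | px | input side of Inception-style classifiers; patches are bilinearly resized 300→299 |
| `channel_range_max` | 20 | 8-bit levels | background clause 1: a patch whose largest per-pixel channel range is below this has no stain saturation |
| `brightness_threshold` | 220 | grayscale level | background clause 2: pixels at or above this count as bright (near-white slide background) |
| `surface_fraction` | 0.5 | fraction | clause 2 fires when the bright fraction exceeds half the patch surface |
| `threshold` | 0.5 | score | binarization of classifier confidence; real CNNs rarely document this choice, so it is configurable |
| `cluster_size` | 4 | patches | the balanced operating point; 2 = screening (higher sensitivity, more slide-level false positives) |
| `connectivity` | 4 | — | edge-sharing neighbours; the stricter reading (a 2×2 square is 4-connected), 8 available by flag |
| `sensitivity` / `specificity` | 0.95 / 0.99 | probability | the patch-level operating point at which the cluster rule controls patient-level error; the simulated classifier reproduces it exactly |
| `score_dispersion` | 4 | — | concentration of the simulated score density within each side of the threshold |

## Design choices where the design was open

**Background clause semantics.** Two readings of the filter criteria are
possible at pixel vs patch granularity, and a literal reading of the
brightness clause ("more than half the surface *below* 220") would discard
dark stained tissue while keeping white background — the opposite of the
filter's purpose of removing background while keeping as many tissue
patches as possible. The package computes clause 1 on the per-pixel channel
range maximized over the patch (low colour saturation everywhere), and
clause 2 flags patches whose *bright* fraction exceeds `surface_fraction`.
The literal direction is retained behind `bright_is_background = FALSE` for
sensitivity experiments. Both clauses are pixel-set statistics, so the
decision is permutation-invariant, and flagging is monotone in both
thresholds.

**Grayscale.** No conversion formula is standard in pathology tooling;
ITU-R BT.601 luma ($0.299R + 0.587G + 0.114B$, rounded) is used and
documented.

**Partial edge tiles** are dropped (floor division): non-overlapping
fixed-size patches admit no partial tile, and padding would fabricate
pixels.

**Normalization order.** "Center by the image mean, map $[0,255]$ to
$[-1,1]$" is ambiguous about order. The package centers by the scalar
pooled-channel mean first, then scales by $2/255$ and clips to $[-1, 1]$;
both orders agree when the mean is 127.5, and clipping guarantees the range
contract. The mean is per *patch* (not per slide) — the quantity available
at inference time — with `per_channel_mean = TRUE` as the variant.
Values within ±127.5 of the mean survive the round trip to within one
8-bit quantum; larger deviations are clipped by contract.

**Bilinear resize convention.** Resampling uses align-corners mapping
(output sample $i$ of $t$ at source coordinate $i(s-1)/(t-1)$), which
preserves the four corner pixels and maps constants to constants. The
convention matters: a $2\times2$ checkerboard upscaled to $3\times3$ has
centre value exactly 127.5 under this convention and other values under
centre-aligned ones. Output is left real-valued so normalization loses
nothing to rounding.

**Cluster rule reading.** The rule is "any maximal connected component of
size ≥ k", *not* "contains a k-square motif": a square is one example of a
qualifying cluster, and component-size thresholds are the standard form of
cluster-extent inference. 4-connectivity is the default because it is
stricter (every 4-connected set is 8-connected); the 8-connected variant is
a flag.

**Simulated score family.** A score must sit on the correct side of the
threshold with exactly the configured probability, yet be continuous for
ROC work. The package draws the side as a Bernoulli (sensitivity for
cancer, specificity for normal) and then draws within the side from a
truncated power density $\propto x^{d-1}$ oriented toward the class mode
(1 for cancer, 0 for normal), $d$ = `score_dispersion`. The operating point
therefore holds *exactly* for any $d$ — dispersion only shapes the score
histogram. Patch scores are independent given truth; spatially correlated
classifier noise is deliberately not modelled (see limitations).

**Evaluation conventions.** Sensitivity/specificity are reported as `NA`
(undefined), never 0, when their class is absent. ROC/AUC is computed by
trapezoidal integration over all thresholds (equal to the Mann–Whitney
statistic $P(\text{pos} > \text{neg}) + \tfrac12 P(\text{tie})$; the test
suite enforces agreement to $10^{-9}$ against pairwise enumeration).
Cohen's kappa is the unweighted binary form, with $K = 1$ when both raters
are constant and identical ($p_e = 1$ forces $p_o = 1$). The paired
Wilcoxon signed-rank test drops zero differences, uses the exact
distribution up to $n = 25$ nonzero untied differences and the
tie-corrected normal approximation beyond, and returns $p = 1$ by
convention when all differences are zero. No multiple-testing correction
is applied to pairwise comparisons by default. Bootstrap confidence
intervals for averaged metrics are percentile intervals over 10,000
seeded resamples.

## What the simulator emulates — and what it does not

`simulate_truth()` plants rectangular (or random-walk blob) lesions on a
patch lattice with an independent-Bernoulli tissue mask. The defaults mirror
the documented scale of clinical material: ~5000 tissue patches per slide
(a 71 × 71 lattice) and lesions covering 10–50% of the grid, the range
reported for most clinical slides. `render_slide()` draws non-tissue cells
as near-white zero-saturation noise and tissue as a two-colour
stain-like checkerboard, constructed so that the background filter recovers
the planted mask exactly — it validates the geometry of the tiling/filter
path, not stain realism.

Passing tests on this generator demonstrate that the aggregation rule, its
closed-form error behaviour, and the pipeline plumbing are correct under
the stated independence assumptions. They do **not** demonstrate clinical
performance: real patch classifiers make spatially correlated errors
(stain artefacts, folds, blur), lesions are not rectangles, tissue masks
are not Bernoulli fields, and real slides vary in size and patch count.
Numbers produced by the simulator characterize the *rule*, not any
particular trained network.

## Numerical and degenerate-input conventions

* Tiling a slide smaller than one patch is an error (an empty grid is
  never silently produced); an all-background slide yields a valid grid
  with an all-false tissue mask, and diagnosing a grid with no tissue
  returns a negative call with a warning.
* Binarization uses `score >= threshold`, so threshold 0 marks every
  tissue patch positive and threshold 1 only exact-1 scores.
* Non-tissue cells are non-positive and break connectivity.
* Clusters are reported sorted by decreasing size; members in column-major
  order. Ties between equal-size clusters keep the component ordering of
  the underlying graph traversal (no semantic meaning attaches to it).
* All Monte Carlo entry points take a `seed` and restore the caller's RNG
  state; equal seeds give bit-identical label draws and TSV outputs.
* File formats carry 0-based, row-major, half-open pixel conventions in
  their headers; in-memory R objects use 1-based matrix indexing.

## Problem sizes used in the checks

The package's own test suite and `scripts/acceptance.R` use: exhaustive
enumeration of all 512 binary 3×3 lattices plus 1000 random 20×20 lattices
against a flood-fill oracle (both connectivities); 2000 replicates of
1000-patch negative slides for the $k=1$ closed form; 20,000 replicates for
the isolated-lesion $s^4$ closed form; $10^5$ draws for operating-point
recovery against a 99% binomial interval; and 500 replicates per class at
the 71 × 71 slide scale for the cluster-size operating table. These sizes
put the Monte Carlo standard errors well below the effect sizes being
checked.

```{r example}
oc <- estimate_operating_characteristics(
  n_rows = 20, n_cols = 20,
  classifier_cfg = simulated_classifier_config(),
  cluster_sizes = c(1, 2, 4, 8), n_reps = 50, seed = 1)
oc[, c("cluster_size", "slide_sensitivity", "slide_FPR")]
```

## Known limitations

* No spatial correlation in simulated classifier noise; real networks'
  false positives cluster around artefacts, which makes the closed-form
  FPR bounds optimistic for small $k$.
* The simulated classifier scores from ground truth, so it cannot measure
  anything about image content; real classifiers plug in through
  [patch_classifier()] / [as_score_grid()].
* Pyramidal scanner formats are out of scope; export a level to PNG/TIFF
  first.
* Stain normalization is not performed; the background filter is the only
  image-level preprocessing besides resize/normalize.
* The heatmap's white-on-dark monochrome map shows raw confidences, not
  binarized calls.
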