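---
title: "Quantifying nascent cellulose networks from confocal stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nascent cellulose networks from confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilquant)
```

## The measurement problem

Protoplasts — plant cells stripped of their wall — regenerate a new
cellulose network within hours in culture. Stained with Calcofluor White,
the nascent network appears under a confocal microscope as bright
curvilinear threads of bundled cellulose fibrils on a dark, roughly
disc-shaped cell. Judging such images by eye does not scale and cannot be
compared across treatments, so this package reduces each imaged cell to
five scalar configuration metrics:

* **total length** — the spread of the network;
* **mean intensity** ($\bar{i}$) — the amount of deposited, stained material;
* **skewness** ($S$) of the skeleton-pixel intensity distribution — a proxy
  for fibril bundling;
* **parallelness** ($P$) — orientation order of the network;
* **average angle** ($\Delta\theta$) — the offset between the mean fiber
  axis and the cell's long axis.

The processing chain is: maximum-intensity projection of the z-stack →
extraction of a one-pixel-wide skeleton of the curvilinear structures →
restriction of the skeleton to the cell region → metric computation.

## The metrics

Let $N$ be the number of skeleton pixels after masking, $i_n$ the
fluorescence intensity at skeleton pixel $n$, and $\bar{i}$ their mean.
Total length is $N$ times the pixel size converted to millimetres; a
diagonal-corrected variant (diagonal pixel adjacencies weighted by
$\sqrt{2}$) is reported alongside as the better arc-length estimator, while
the raw pixel-count definition is retained as the primary column.

Skewness uses population (biased) moments throughout:

$$ S = \frac{1}{N}\sum_{n=1}^{N}\left(\frac{i_n - \bar{i}}{\sigma}\right)^3,
\qquad \sigma = \sqrt{\frac{1}{N}\sum_{n=1}^{N}(i_n-\bar{i})^2}. $$

A handful of disproportionately bright bundle pixels over many dim
single-fibril pixels produces a long right tail and a large positive $S$;
$S$ is invariant under affine intensity maps $i \mapsto a\,i + b$ ($a>0$),
so staining and detector gain do not affect it.

Orientation statistics are built on unordered pairs of 8-adjacent skeleton
pixels, whose connecting vectors on the square lattice fall in exactly four
axial classes: $0^\circ, 45^\circ, 90^\circ, 135^\circ$, counted as $n_0,
n_{45}, n_{90}, n_{135}$. Parallelness is the normalized contrast between
orthogonal classes:

$$ P = \frac{|n_0 - n_{90}| + |n_{45} - n_{135}|}{n_0 + n_{45} + n_{90} + n_{135}}, $$

1 for a perfectly parallel skeleton and 0 for an isotropic one. The mean
fiber orientation $\theta_{\mathrm{cellulose}}$ is the doubled-angle
(axial) circular mean over the four classes. Two implementation choices
matter here:

* Diagonal pairs are weighted by $\sqrt{2}$ — their physical length — in
  the circular mean. With unit weights the four-class quantization biases
  the recovered angle by up to $\approx 5^\circ$ at intermediate
  orientations; length weighting bounds the bias below $\approx 2^\circ$.
  (The plain unit-weight axial mean is available as `axial_mean()`.)
* The angular offset to the cell's long axis is computed with the verbatim
  piecewise rule $\Delta\theta = d$ if $d = |\theta_{\mathrm{protoplast}} -
  \theta_{\mathrm{cellulose}}| \le 90$, else $d - 90$. This rule is *not*
  the standard axial distance $\min(d, 180-d)$ (it maps $d = 170^\circ$ to
  $80^\circ$ rather than $10^\circ$) and is consequently not invariant
  under joint rotation of cell and network when the mod-180 wrap crosses
  the $90^\circ$ breakpoint. Both values are reported: `delta_theta`
  (verbatim, the CSV column `delta_theta_deg`) and `delta_theta_axial`.

Undefined metrics (empty skeleton, constant intensities, no adjacent pairs,
perfectly balanced orientation mass) propagate as `NA` plus a reason code —
never as 0, because 0 is a meaningful value for both $S$ and $P$.

## Skeleton extraction

The extraction stage mirrors a line-extraction plugin workflow whose five
printed parameters it adopts: `giws_iter = 8` smoothing iterations,
`mdnms_len = 7` oriented-kernel length, `pickup = above` (bright lines),
`shave_len = 5` and `del_len = 5` pruning lengths. The plugin's internals
are not public; the stages below are this package's own and were designed
against ground-truthed synthetic scenes.

**Gaussian-weighted iterative smoothing.** Each of the `giws_iter`
iterations blends a Gaussian-blurred copy ($\sigma = 1$ px) into the image
with a per-pixel weight $w = 1/(1 + (g/\bar g)^2)$, where $g$ is the local
gradient magnitude *dilated over a 3×3 neighbourhood* and $\bar g$ its
image mean. The dilation is essential: at a ridge crest the raw gradient
vanishes, so an undilated weight smooths exactly the crest pixels and
erodes the lines the stage exists to preserve; dilated, crest pixels
inherit their flanks' gradient and stay crisp while the background is
flattened. A constant image is a fixed point and the output is bounded by
the input maximum.

**Oriented line response.** For each of 8 directions spaced $22.5^\circ$
over $[0, 180)$, the response is the mean intensity along a centred
`mdnms_len`-pixel segment, sampled at nearest-pixel offsets. No
interpolation: determinism, speed, and at most half-pixel error.

**Multi-directional non-maximum suppression.** Suppression runs *per
direction*: a pixel is a candidate when a direction's response exceeds the
pickup threshold and is a local maximum along that direction's
perpendicular; candidates are unioned over directions. Suppressing only
along the pooled best direction would delete the weaker fiber around every
crossing (near a crossing the weaker fiber never wins the pooled maximum,
but it still crests its own orientation's response). Exact ties break
toward the lexicographically smallest pixel, so extraction is fully
deterministic.

The pickup threshold has two relative tiers, both scaling linearly with
intensity (the skeleton is therefore invariant under uniform intensity
scaling): (i) median + `pickup_k` × 1.4826 MAD of the smoothed image
(`pickup_k = 3`, i.e. three robust SDs above background — a mean/SD
threshold fails here because the bright-bundle tail of fibril images
inflates the SD past the single-fiber ridge response); (ii) 35% of the
response level above which 75% of the total candidate response mass lies,
which removes the faint arc-shaped end artifacts of the oriented kernel
while keeping genuinely dim fibers (near-zero phantom crests carry no mass
and cannot drag the reference down; bright bundles are capped by their mass
share).

Per-direction crests of neighbouring orientations interleave diagonally
around oblique lines — a pattern plain thinning cannot reduce — so the
candidate set is consolidated: single-pixel holes with ≥ 4 foreground
neighbours are filled (2-px gaps between genuinely distinct parallel fibers
are never bridged) and the band is reduced to its medial axis.

**Pruning.** Zhang–Suen thinning to one-pixel width, then iterated
shaving of terminal branches of at most `shave_len` pixels (a spur's base
pixel is absorbed when, without the branch, its remaining neighbours still
form one 8-connected cluster — arms of a true crossing stay apart and are
never touched), then deletion of connected components of at most `del_len`
pixels. Dot-like callose signals are removed by this component filter
rather than a dedicated detector. Thinning sub-passes are directional, so
$90^\circ$ rotation covariance of the full extraction is near-exact
(≈ 99% of pixels) rather than bit-exact; the metric-level rotation
invariances hold exactly.

## Cell region and shape class

The cell region comes from a user mask, or from an automatic fallback
(Gaussian blur $\sigma = 5$ px → Otsu threshold → largest component → hole
filling → closing) standing in for manual segmentation. The region's
ellipse is fitted from second moments of the mask; the aspect-ratio rule
classifies cells as spherical versus oval at aspect ratio > 1.05. The
"deformed/bud-shaped" class has no published quantitative rule; this
package uses solidity (mask area over convex-hull lattice area) < 0.95,
taking precedence over the oval rule. Both thresholds are exposed.
Masking the skeleton re-applies the shave/delete rules so that boundary
clipping cannot leave sub-threshold fragments; it never adds pixels.

## The synthetic scene generator

Every quantitative claim about the pipeline is validated on scenes with
known ground truth, because no deposited raw imaging exists to test
against. `generate_scene()` emulates a Calcofluor-stained protoplast:

* a disc-shaped cell (default semi-axes 90 × 75 px at 0.2 µm/px ≈ a 35 µm
  protoplast in a 256² field);
* `n_fibers = 60` smooth random polylines (step 4 px, heading jitter
  SD 4°, target lengths 60–180 px) clipped to the cell, orientations
  uniform or axial von Mises (doubled-angle construction, since fibers are
  undirected);
* bundling: a `bundling_fraction` share of fibers is partitioned onto
  shared paths by a Chinese-restaurant process whose concentration falls
  as bundling rises ($\theta = 6(1-b)/b$), giving a smooth, heavy-tailed
  bundle-thickness distribution; co-located fibers add their intensities,
  and a bundle of $k$ fibers is drawn at $1/\sqrt{k}$ of the single-fiber
  length (thick bundles are short, compact structures). This construction
  is what makes measured skewness rise monotonically with the bundling
  fraction, as a bundling proxy must; a naive equal-size bundle split
  instead *lowers* skewness at high bundling because the bright-pixel
  share grows until the distribution is merely bimodal;
* rendering: per-fiber intensity 3000 DN with 15% lognormal jitter,
  stamped on Bresenham rasters, spread by a Gaussian line profile
  (σ = 1.5 px), then per-slice Poisson photon noise (0.5 photons/DN) plus
  Gaussian read noise (SD 2 DN) on 3 slices of shared geometry, so the
  projection path is exercised end to end on 16-bit data.

Ground truth (polylines, rasterized centerlines, analytic arc length,
length-weighted mean orientation) is emitted alongside.
`generate_regimes()` recasts the two microtubule-drug perturbations as
parameter regimes: depolymerization-like keeps 40% of the fibers with
orientations concentrated near the cell's long axis; stabilization-like
raises bundling to 0.75 and keeps 60% of the fibers.

What the generator does *not* emulate: curved-surface (3-D shell)
geometry of a real protoplast, spatially varying background and staining,
callose dots, neighbouring-cell debris, and optical anisotropy. Passing
the synthetic validation therefore shows the measurement chain is correct
and well-calibrated on images with this contrast structure, not that any
particular biological dataset would yield identical values.

## Validation protocol and problem sizes

The shipped test suite and `scripts/acceptance.R` regenerate everything
from seeds; the relevant experiment designs are:

* **Skeleton fidelity**: 20 scenes of 10 non-overlapping-path fibers
  (bundling 0), noise-free and noisy; recall and precision of the
  masked skeleton against the truth centerlines at 1-px tolerance.
  Sparse scenes are the right instrument here: with 60 crossing fibers and
  a 1.5-px PSF, close-parallel fibers merge optically and no centerline
  extractor could separate them — that is a property of the optics, not of
  the algorithm under test.
* **Orientation recovery**: 10 concentrated scenes (κ = 25, µ = 65°);
  mean absolute error of the recovered mean fiber angle.
* **Length recovery**: 10 scenes of 6 short fibers whose centerlines stay
  ≥ 2 px apart (`scene_paths_disjoint()`), against the diagonal-corrected
  length; crossings would otherwise confound skeleton length with junction
  geometry.
* **Regime discrimination**: 20 seeds × {control, depolymerization-like,
  stabilization-like}, compared by the package's own Mann–Whitney test.
* **Bundling/orientation monotonicity**: median S over 20 seeds at
  bundling 0.2→0.8 and median P at κ = 0.5→30, as rank correlations. The
  bundling sweep starts at 0.2 because at near-zero bundling incidental
  fiber crossings — themselves 2× intensity points — dominate the tail, so
  the lowest levels are not resolvable by any intensity-skewness measure;
  S saturates above bundling ≈ 0.8.

Scene sizes (256², ≤ 60 fibers) keep the full suite in minutes on one
core while leaving every effect far larger than its seed-to-seed noise.

## Statistical comparison

`mann_whitney()` wraps the two-sided rank-sum test: exact when both groups
have ≤ 20 observations without ties, otherwise the normal approximation
with tie and continuity correction; an all-tied comparison degenerates to
p = 1 with a warning. Stars follow the two-tier convention (`**` p < .01,
`*` .01 ≤ p < .05) exactly at the boundaries. Per the source convention no
multiple-testing correction is applied per metric, but `compare_groups()`
emits a Holm-adjusted column alongside.

## Known limitations

* Sub-pixel ridge localization and junction-aware tracing of individual
  fibrils are out of scope; lengths are digital-curve estimates.
* The raw total-length definition (pixel count × pixel size)
  systematically undercounts oblique fibers by up to ~10% on average;
  use `total_length_corrected_mm` when absolute lengths matter.
* Anisotropic xy pixels are rejected, not resampled.
* The verbatim Δθ rule's behaviour past the 90° breakpoint is preserved
  from the source definition; use `delta_theta_axial` for a metric with
  standard axial-distance semantics.
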