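---
title: "Spatially regularized fuzzy c-means superpixels: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially regularized fuzzy c-means superpixels: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smbft)
```

## The problem

Superpixel algorithms partition an image into small, perceptually
homogeneous, connected regions that downstream analyses treat as atomic
units. Most classical methods (SLIC-family, Turbopixel, SEEDS) assign each
pixel to exactly one candidate region at every step. On images with
genuinely fuzzy boundaries — brain MR slices are the motivating case, where
partial-volume effects blur the white-matter / gray-matter / CSF interfaces
— that binary commitment misclassifies boundary pixels, and single
superpixels end up straddling several tissues.

SMBFT (superpixel method based on fuzzy theory) replaces the hard
assignment with fuzzy c-means (FCM) memberships, so boundary pixels carry
graded evidence until the very end, and adds two regularizers that plain
FCM lacks:

* a **coordinate-distance term** that keeps each cluster spatially compact
  and prevents clusters from crossing each other, which is what turns an
  intensity clustering into a superpixel method; and
* an **8-neighborhood term** that scores each pixel's neighbors against the
  candidate cluster center, so isolated noisy pixels cannot flip their
  assignment.

## The objective and its block minimizers

With memberships $u_{ik}\in[0,1]$ (cluster $i$, pixel $k$,
$\sum_i u_{ik}=1$), intensity centers $v_i$, coordinate centers
$(X_i,Y_i)$, fuzzifier $p>1$, and pixel values $y_k$ at integer coordinates
$(X_k,Y_k)$:

$$
J \;=\; \sum_{i=1}^{c}\sum_{k=1}^{N} u_{ik}^{\,p}\Big[\,
\underbrace{\lVert y_k - v_i\rVert^2}_{\text{intensity}}
+ \alpha\underbrace{\big((X_k-X_i)^2+(Y_k-Y_i)^2\big)}_{\text{compactness}}
+ \frac{\beta}{N_R}\underbrace{\sum_{r\in N_k}\lVert y_r - v_i\rVert^2}_{\text{neighborhood}}
\Big].
$$

Setting the Lagrangian derivatives to zero under the sum-to-one constraint
gives closed-form updates, which `run_smbft()` alternates:

* memberships: $u_{ik} = 1\big/\sum_j (E_{ik}/E_{jk})^{1/(p-1)}$ with
  $E_{ik}$ the bracketed effective distance (`update_membership()`);
* intensity centers: a weighted mean of each pixel value plus its
  neighborhood sum (`update_intensity_centers()`);
* coordinate centers: membership-weighted centroids
  (`update_coordinate_centers()`).

Each update is the exact minimizer of its block, so $J$ is non-increasing
across iterations; the test suite asserts this on every traced run. One
consequence drove an implementation choice: pixels at the image border have
fewer than 8 neighbors. We sum the neighborhood term over the neighbors
that exist while keeping the normalizer $N_R = 8$ fixed, and accordingly
the intensity-center denominator uses the *actual* neighbor count $n_k$,
$\sum_k u_{ik}^p (1 + \beta n_k / N_R)$. On interior pixels this is the
familiar $(1+\beta)\sum_k u_{ik}^p$; using that simpler form everywhere
would make the center update only an approximate minimizer at the border
and could (marginally) break monotonicity, so we prefer the exact
stationary point.

Hard labels are the per-pixel membership argmax, ties to the lowest cluster
index. The iteration itself contains no randomness: identical inputs give
bit-identical outputs.

### Degenerate cases

* If some effective distance is exactly zero (a pixel coincides with a
  center in both value and position on a locally constant patch), the pixel
  is assigned crisply to the lowest-index zero-distance cluster.
* A cluster whose total membership weight vanishes keeps its previous
  center and a warning is raised; this does not occur in practice with
  grid seeding.
* Very small distances are divided by the column minimum before the
  negative power $(\cdot)^{-1/(p-1)}$ is taken, so no overflow occurs.
* `max_iter = 0` returns the nearest-seed labeling under the combined
  intensity/coordinate distance, which is a useful baseline.

## Parameters

| parameter | default | units / scale | role |
|---|---|---|---|
| `k` | — | count | requested superpixels; the grid may seed slightly more |
| `alpha` | 2 | (intensity/pixel)$^2$ | compactness weight; useful range about 1–10, smaller for larger `k` |
| `beta` | 1 | dimensionless | neighborhood (noise) weight |
| `n_r` | 8 | count | neighborhood normalizer, fixed at 8 |
| `p` | 2 | dimensionless | fuzzifier; 2 is the standard FCM convention (no canonical value exists for this model, so we expose it) |
| `tol` | 1e-3 | native intensity units | convergence threshold on the largest center change |
| `max_iter` | 100 | count | iteration cap |
| `min_size` | $\lfloor S^2/4\rfloor$ | pixels | post-merge size threshold, a quarter of the expected superpixel area ($S=\sqrt{MN/k}$ is the grid side) |

Intensities are used on the raster's native scale (0–255 for the bundled
readers); `tol` is interpreted on that scale and nothing is silently
normalized. For color images the pipeline runs in CIE L\*a\*b\* (D65,
standard sRGB companding), where Euclidean distance is perceptually
meaningful; `alpha` is not rescaled for Lab's different numeric range and
remains user-controlled.

Initialization follows the usual grid construction: cells of side
$S=\sqrt{MN/k}$ ($\lceil M/S\rceil\times\lceil N/S\rceil$ cells, remainder
pixels assigned to the leading cells), each seed at its cell center, then
moved to the lowest-gradient pixel of its $3\times3$ window (squared
central differences, one-sided at the border, summed over channels for
color). The move is deterministic — ties break to the lowest row-major
index — because a minimum-gradient rule needs no randomness to avoid
seeding on an edge.

An optional *windowed* assignment mode restricts each pixel to clusters
whose coordinate centers lie within $2S$; it reduces the $c\times N$ cost
but changes results, so it is off by default and excluded from the
evaluation runs.

## Postprocessing

Fuzzy argmax labels need not be connected. `postprocess_labels()` first
splits every label into its 4-connected components (4-connectivity
throughout, to prevent diagonal leaks between regions), then merges every
region smaller than `min_size` into its 4-adjacent neighbor with the
closest mean intensity (Euclidean over channels). Small regions are
processed in increasing size order with means frozen at the start of a
pass, which makes the outcome independent of incidental ordering; passes
repeat until no region is undersized, so the operation is idempotent.

## Evaluation metrics

* **Undersegmentation error**:
  $UE=\sum_i\sum_{k:S_k\cap R_i\neq\emptyset}|S_k\setminus R_i| / \sum_i|R_i|$.
  Any nonzero overlap counts — there is no minimum-overlap tolerance — so
  values can exceed those of more forgiving UE variants.
* **Boundary recall**: the fraction of ground-truth boundary pixels
  (4-neighbor label change; image borders are not automatically boundary)
  whose Euclidean distance to the nearest superpixel boundary pixel is
  *strictly* less than $\varepsilon$ (default 2). Because boundary pixels
  sit at integer coordinates the test is exact, implemented as a dilation
  by all integer offsets with squared norm $<\varepsilon^2$.
* **Average accuracy rate**: $AAR=\mu(1-UE)+(1-\mu)BR$, default
  $\mu=1/2$; a single number for ranking methods when both criteria
  matter. $AAR=1$ exactly at the ideal $UE=0$, $BR=1$.
* **Superpixel entropy** for gray images without ground truth. The
  default *histogram* variant is the Shannon entropy of each superpixel's
  256-bin intensity histogram — 0 for a homogeneous region, growing with
  internal diversity, which is the intended reading ("more single medium,
  smaller entropy"). A *literal* variant that normalizes the raw pixel
  values themselves ($p_j=x_j/\sum x_j$) is kept behind a flag; note it
  evaluates to $\ln n$ on any uniform $n$-pixel region, so it does not
  order segmentations by homogeneity, which is why it is not the default.

In the degenerate limit where every pixel is its own superpixel, $UE=0$
and $BR=1$ identically; the acceptance suite verifies this analytic
extreme.

## The phantom generator

`generate_phantom()` builds the desk-scale stand-in for simulated brain-MR
data: a piecewise-constant template (vertical stripes, nested rectangles,
or a brain-like nest of ellipses — background, a gray-matter-like ring and
a white-matter-like core for the default three intensities 20/120/200),
optionally blurred at the boundaries, multiplied by a smooth bias field,
plus additive Gaussian noise, clamped to [0, 255]:

* **noise**: $\sigma = \mathrm{noise\_pct}/100 \times$ (template intensity
  range). The study conditions of interest are 0%, 5% and 7%.
* **bias field**: $1 + (\mathrm{bias\_pct}/100)\cos(\pi r/(H-1))
  \cos(\pi c/(W-1))$ — a product of half-period cosine ramps spanning
  $1\pm\mathrm{bias\_pct}/100$, mimicking MR shading at amplitudes 0% or
  40%. It is smooth and multiplicative but not a physical coil model.
* noise is Gaussian, not Rician as in real MR magnitude images; the
  phantoms exercise robustness, they do not emulate MR physics, and
  anatomy is schematic (no cortical folding, no partial-volume mixtures
  beyond optional Gaussian blur).

The ground truth is the template labeling and is independent of noise,
bias and seed; images are fully determined by `rng_seed`. Passing tests on
these phantoms therefore demonstrates correct optimization, noise
robustness and boundary adherence under controlled conditions — not
performance on real natural-image benchmarks or simulated MR volumes,
which have texture, illumination and anatomy the generator deliberately
omits.

## Problem sizes used in the shipped studies

The test suite runs the full pipeline on $128\times128$ three-region brain
phantoms with $k\in\{50,100,200\}$ (noiseless trend study) and at
$k=100$ with 5% noise and a 40% bias field (recovery and
neighborhood-benefit studies); objective monotonicity is additionally
traced on ten seeded $48\times48$ phantoms at $k=16$. These sizes keep a
global $c\times N$ assignment — the algorithm's known cost driver —
comfortable on a single CPU while leaving every boundary many pixels long;
the trends they probe (UE falling and BR rising with $k$, both tending to
their extremes) are scale-free.

## Known limitations

* The global assignment is $O(cN)$ per iteration; large images with large
  $k$ are slow unless the windowed mode is enabled (which alters results).
* $\alpha$ must be chosen by the user; no mapping from $k$ to $\alpha$ is
  provided because none is established.
* 2-D rasters only; volumes must be processed slice-wise.
* The entropy criterion applies to grayscale images only.
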