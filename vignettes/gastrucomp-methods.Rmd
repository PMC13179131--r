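---
title: "Methods: quantifying cell competition in mosaic gastruloids"
author: "gastrucomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cell competition in mosaic gastruloids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastrucomp)
```

## The measurement problem

A mosaic gastruloid is a 3D aggregate seeded from two labelled embryonic
stem cell clones — here called the mCherry and emiRFP populations after
their nuclear fluorophores. Cell competition between the clones manifests
as (i) stagnating counts of the loser population after a developmental
gate, (ii) apoptotic elimination of loser cells, (iii) shifts in marker
protein levels (p53) in cells neighbouring a fitter clone, and (iv) no
spatial segregation of the clones. Each readout rests on a chain of image
quantification steps. This vignette records the models behind each step,
the tunable parameters with their defaults and units, the numerical
choices, and what the synthetic tests do and do not establish.

## Validating segmented objects

Upstream 2D segmentations, concatenated across z-planes by label identity,
arrive as integer label stacks. An object becomes a cell when it spans at
least two *consecutive* z-planes and its centre-plane area lies within
bounds. The centre plane is the z-plane with the highest summed
fluorescence inside the mask (ties resolve to the lower plane index, a
deterministic and documented choice; the channel defaults to the object's
own segmentation channel, since no single channel is canonical). The cell
centre is the 2D area centroid of the centre-plane mask plus the physical
plane z; all per-channel means are taken on the centre plane only, which
minimises crosstalk from neighbouring nuclei in dense tissue.

### The KDE minimum-area threshold

The lower area bound separating nuclei from debris is data-driven: a
Gaussian KDE is fitted to the centre-plane area distribution over an
ascending bandwidth grid (geometric, 0.5–20 µm² in 40 steps by default),
and the threshold is the interior local minimum of the first bandwidth
whose density has exactly one such minimum. Two numerical choices matter:

* the evaluation domain spans the 0.5th–99.5th percentiles of the areas
  (512 points). A domain anchored at zero would make the selected
  bandwidth depend on the absolute location of the data and break
  translation equivariance;
* the single-minimum configuration must persist across a 2.5-fold
  bandwidth range (`stability = 2.5`). Gaussian-KDE mode counts decrease
  through one *en route* to zero as the bandwidth grows, so a noisy but
  unimodal sample always passes through a fleeting single-minimum state;
  requiring persistence distinguishes a genuine debris/cell separation
  (which on separably bimodal samples persists across a ≥ 7-fold range)
  from smoothing transients (≤ ~2-fold). Without a stable minimum the
  estimator raises a typed error and the caller may fall back to a
  constant.

The selected threshold is the KDE minimum, not the minimum of the
underlying density: at the separating bandwidths the KDE's component
spreads are inflated by the kernel (sd² + h²), which displaces the minimum
towards the wider component — on a deep-valley mixture such as
0.3·N(8, 2²) + 0.7·N(60, 10²) by roughly 15–25% upward. Any threshold
inside the near-empty valley classifies identically in practice, but the
displacement is a real property of the estimator worth knowing. The upper
bound defaults to 200 µm² (a nucleus-size sanity cap).

## Spatial statistics

All distances are in µm, computed in 3D from the stored cell centres; the
default voxel spacing is 1 × 1 × 2 µm (x, y, z), a typical confocal
anisotropy, and is always explicit in the data structures rather than
implicit in pixel units.

**Radial position.** `P = Dc / (Dc + De)` with `Dc` the distance to the
gastruloid centroid and `De` the distance to the nearest boundary point.
The centroid is the unweighted mean of the validated cell centres —
computable from the cell table alone; a mask-volume centroid is a
reasonable alternative when masks are at hand. Boundaries are extracted
per z-plane (gastruloids are irregular, so no parametric shape is
assumed) by morphological Chan–Vese active contours: the binary level set
switches boundary pixels to the nearer region mean and is then smoothed by
a morphological closing/opening pass, until stable (cap 200 iterations;
non-convergence raises a condition carrying the last contour). The traced
contour runs through boundary-pixel centres and is pushed half a pixel
along the outward normal so that it follows the pixel outer edge; `De` is
then the minimum distance to the boundary polygons of *all* planes after
densifying each polygon to ≤ 1 µm edges, which bounds the discretisation
error of the nearest-vertex query by 0.5 µm. A centre that falls outside
its plane's boundary is flagged and assigned P = 1 rather than dropped.

**Local density.** `rho = (mean of d³ over the n nearest neighbours)^-1`
(µm⁻³, default n = 20). Neighbours closer than 0.25 focal-cell diameters
are excluded first — doubly-segmented nuclei otherwise produce near-zero
distances that dominate the cubic mean. The cell diameter is the
equivalent-circle diameter `2·sqrt(centre_area/pi)`, the only estimate
available from the stored record. Whether apoptotic objects should count
as neighbours is genuinely open; the `candidates` argument lets callers
exclude them, and the high-level wrapper keeps all validated cells.

**Neighbourhood composition.** Fractions over the k = 20 nearest nuclei.
The normalised variant divides by the gastruloid-wide population fraction,
so 1 means the neighbourhood mirrors the global mix; this normalisation is
an interpretation (the natural reading of a "normalized percentage" of
neighbours) and is isolated in its own column so any other convention can
be applied downstream.

Neighbour queries are exhaustive vectorised searches. At the instance
sizes this pipeline sees (≤ a few thousand cells per gastruloid) an
exhaustive query is faster than building a spatial index, and its results
are by construction identical to the brute-force definition the tests
assert against.

## Marker quantification

The marker channel (p53 immunostaining in the motivating application)
suffers linear spillover from the bright H2B–mCherry channel plus a
depth-dependent baseline. The model is

C_obs(z) = C_true + b0(z) + s · B(z) + noise,

with `s` global for an imaging session and `b0(z)` per plane. `s` is
fitted on secondary-antibody-only controls (where C_true = 0) by pooled
OLS over in-cell pixels with per-plane intercepts absorbed via
within-plane centering — the per-plane baselines then never bias the
slope. "In-cell" defaults to the union of nuclear label masks. `b0(z)` is
the per-plane *median* of `C_obs − s·B`, robust to a minority of
contaminated pixels; planes without in-cell pixels are linearly
interpolated and flagged. Corrected intensities
`C_corr = C_obs − b0(z) − s·B` are deliberately *not* clipped at zero:
clipping would bias exactly the per-plane medians the model relies on.

Extreme-high cells are gated per plane by Tukey fences,
`tau_z = Q3_z + 4.5·IQR_z`, with type-7 (linear interpolation) quartiles —
the common convention, configurable since none is canonical — and a
*strict* inequality at the fence. Per-plane gating absorbs any residual
depth dependence. Planes with fewer than 4 cells are merged with the
nearest plane and flagged. At multiplier 4.5 the Gaussian-null tail beyond
the fence is ≈ 3×10⁻¹⁰, so essentially no cell is flagged unless the
plane's distribution genuinely has an extreme tail.

Cells segmented in both channels are disambiguated by k-means (k = 2) on
the two channel means with deterministic farthest-pair initialisation
(reproducibility without a hidden RNG state); the cluster with the higher
mCherry mean is the mCherry population, and cells whose segmentation
channel disagrees with their cluster are excluded with a flag. The
nuclear/cytoplasmic ratio subtracts compartment-specific backgrounds
(from secondary-only samples) before dividing; a non-positive cytoplasmic
denominator yields NA with a flag rather than a spurious ratio.

## Apoptosis staging

Stages follow a deterministic morphology decision table: early = intact
nucleus with cytoplasmic Casp3; mid = nuclear membrane disintegration,
nuclear Casp3 and chromatin granules; late = reduced nuclear size with
fully compacted chromatin. Contradictory flag combinations are
unclassifiable and flagged for curation rather than forced. Early and mid
events arrive as manually curated records (their segmentation is not
automatable at acceptable fidelity); only late-event filtering is
automated: candidates must exceed the 90th percentile (type 7, consistent
throughout the package) of early-event Casp3 means *and* clear a
KDE-derived debris size cut reusing the minimum-area machinery. Events are
attributed to a population by dividing each channel mean by the median of
that channel over viable cells of the owning population — "normalisation"
is otherwise underspecified, and a per-population robust scale makes the
two channels commensurable; ties are left unassigned.

## Competition statistics

Effect sizes are per-gastruloid focal counts divided by the arithmetic
mean (configurable; the median is the obvious alternative) of the focal
value in a reference condition at the matched time point. Growth curves
are `N_t/N_0` with a pooled log-linear doubling-time fit over a stated
window, defaulting to the first 48 h (the pre-gate exponential phase).
The washout model is ideal serial dilution,
`c_n = c0 ((V − v)/V)^n`, assuming complete mixing before each removal:
with c0 = 100 nM, V = 190 µl, v = 150 µl, n = 4 it gives 0.196 ≈ 0.2 nM.
Percentages are rounded half-up (150 + 2 seeding → 1.3% supercompetitors).

## Morphometry

Widefield channels are summed, blurred (Gaussian sigma 0.6 px — a pixel
-space parameter, with the pixel size recorded separately for µm
conversion), thresholded by Kapur maximum entropy over a 256-bin histogram
(bin count unstated upstream; 256 matches 8-bit practice), filtered to
components ≥ 5000 px, hole-filled, and measured: area, and aspect ratio as
the major/minor axis ratio of the second-moment fitted ellipse (the
ImageJ convention). When several components survive, the largest is
measured and the count reported. Maximum-entropy thresholds sit low on the
edge-blur skirt, so areas are overestimated by up to
perimeter × ~0.7 px — about 3–4% on a 300-px fixture — which the tests
bound explicitly rather than hide.

## Transcriptome staging

Counts are normalised by median-ratio size factors (median over
all-nonzero genes of count/geometric-mean) then log1p-transformed —
matching the DESeq2 convention, which the test suite cross-checks against.
Staging is the argmin of Euclidean distance to timed reference
pseudobulks on the shared gene set, optionally restricted to the
reference's most variable genes (which gene set was shared upstream is
unstated; HVG restriction is the configurable default recommendation).
The anterior–posterior position of a sample is estimated by building
mixtures `alpha·posterior + (1 − alpha)·anterior` on a grid (default step
0.1), projecting mixtures and query onto the leading principal axis of
the mixture cloud — the mixtures are affine in alpha, so one axis carries
all of their variance — and returning the nearest grid alpha.

## The synthetic generator: what it does and does not emulate

`generate_point_gastruloid()` places nuclei by rejection sampling inside a
smoothly deformed ellipsoid (polar-form radius with low-order angular
harmonics; default semi-axes 80 × 65 × 50 µm) with a hard-core minimum
spacing of 0.8 nominal nucleus diameters (default diameter 8 µm) —
preventing the degenerate zero-distance neighbours that would break
density statistics. Populations are independent Bernoulli draws (uniform
mixing, consistent with the observed absence of clustering), with an
optional radial log-odds bias knob. Channel levels are log-normal within
population, separable by a 2-cluster partition, reflecting clearly bimodal
real distributions; a configurable fraction (default 2%) of cells carries
an 8-fold extreme marker level. `render_image_stack()` draws each nucleus
as an ellipsoidal blob spanning ≥ 2 z-planes and injects the exact
spillover model above. Count time courses are phenomenological piecewise
exponentials (winner rate ln 2/10 h⁻¹, matching ~10-h doubling; gate
48–96 h; Poisson replicate noise; the default stagnation rate programs an
effect ratio of 0.3); there is no mechanistic simulation of signalling or
apoptosis cascades, and no microscopy PSF. Consequently, passing tests
establish the *correctness of the computations* — parameter recovery,
oracle equivalence, closed-form agreement — not the biological fidelity of
any constant, and real-data effect sizes are outside what desk-scale
synthetic data can certify. Fixed seeds regenerate every artefact
bit-for-bit.

Problem sizes used by the test and acceptance runs — 200–2000 cells,
64×64×20 to ~170×140×49 voxel stacks, 100 replicate point clouds of 300
cells, 10,000-cell fence nulls — are the package's chosen verification
scale: large enough for the binomial/Poisson tolerances the tests state,
small enough to run the whole suite in well under a minute.

## Known limitations

* The KDE threshold inherits the smoothing displacement discussed above;
  thresholds on deep-valley mixtures are conservative (shifted towards the
  wider mode).
* `De` is computed against per-plane boundary polygons; between-plane
  boundary interpolation is not attempted, so for very coarse z-steps the
  nearest boundary point can be slightly overestimated near the poles.
* Spillover correction models a single bleed source; multi-source
  unmixing is out of scope.
* Depth correction beyond the per-plane baseline `b0(z)` (e.g. absorption
  models) is not implemented.
* The morphometry step measures the largest surviving component only;
  multi-axis morphologies are reported by count, not categorised.
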