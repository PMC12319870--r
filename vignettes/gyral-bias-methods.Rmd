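---
title: "Vertex-spacing bias in surface fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertex-spacing bias in surface fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Surface-based fMRI analysis discretises the cortical sheet as a triangular
mesh and carries every statistic on its vertices. Standard processing
pipelines place vertices unevenly: evenly spaced vertices on an inflated
sphere map to unevenly spaced vertices on the folded surface, so neighbours
sit closer together in sulci than on gyral crests. Any operation that mixes
signal across nearby locations then couples more vertices in sulci than in
gyri. Two such operations are ubiquitous:

* **volume-to-surface projection** — where vertex spacing is finer than the
  voxel grid, several vertices sample the same voxel and inherit nearly
  identical time series;
* **geodesic Gaussian smoothing** — a kernel of fixed millimetre width
  covers many vertices in sulci and few on crests.

Both inflate the correlation between neighbouring vertices ("local
correlation") preferentially in sulci. Because folding patterns are
individually distinctive, the inflated correlations carry anatomical
fingerprints into what is nominally functional data. This package
implements the full chain — geometry, generator, mechanisms, statistics,
inference, and the downstream consequence experiments — so the bias can be
produced, measured, and tested on synthetic cohorts where the ground truth
(pure noise) is known.

## The core statistic

For vertex $v$ with mesh neighbours $N(v)$ and time series $x_v$, the
**local correlation** is

$$\mathrm{lc}(v) \;=\; \tanh\!\Big(\tfrac{1}{|N(v)|}\sum_{u \in N(v)}
\operatorname{artanh}\, r(x_v, x_u)\Big),$$

the Fisher-averaged Pearson correlation with the neighbours. Correlations
are clipped at $1 - 10^{-12}$ before `artanh` so the transform stays
finite. For fine-scale analyses the map is **normalised** by subtracting,
at each vertex, the unweighted mean of the map over all vertices within a
15 mm geodesic radius (the vertex itself included; on dense meshes the
inclusion is negligible, on coarse synthetic sheets it is not, which is why
the choice is fixed and documented).

Associations between two maps always use the **area-weighted Pearson
correlation**, each vertex weighted by its surface area (one third of each
incident triangle's area), so densely sampled sulci do not dominate.

## The synthetic world

`make_folded_sheet()` builds one participant:

1. a regular triangulated grid (default $64 \times 64$ vertices, 2 mm
   spacing) on a periodic 2D domain — a torus, so the sheet has no edges
   and cyclic translations form an exact symmetry group for permutation
   testing;
2. a **depth field** $d$: a sum of 6 random sinusoids with wavelengths
   16–32 mm (the scale of real gyral widths), random orientations and
   phases per participant, standardised to zero mean and unit variance.
   Positive $d$ is a gyral crest. Out-of-plane folds are $z = A\,d$ with
   $A = 3$ mm;
3. an **in-plane warp** that couples spacing to the folds: vertices are
   displaced by $\beta \nabla \psi$ where $\psi$ solves the Poisson
   equation $\Delta\psi = w$ analytically per sinusoid
   ($\sin(k \cdot x + \phi) \mapsto -\sin(k \cdot x + \phi)/|k|^2$), so
   local area scales as $\approx 1 + \beta w$ — compressed where $w < 0$,
   stretched where $w > 0$.

The warp's driving field is not $d$ itself but the unit-variance mixture
$w = (d + j e)/\sqrt{1 + j^2}$, with $e$ an independent field of the same
spectrum and $j = 0.9$. On real meshes spacing follows the
sphere-registration distortion field, which tracks the folds only
imperfectly; driving the warp with $d$ alone gives a spacing–depth
correlation near 0.85, far above anything observed. With the mixture, the
default world reproduces the empirically observed association: across
seeds, area-weighted $r(\text{spacing}, \text{depth}) \approx 0.52$
(range roughly 0.43–0.65), inside the generator's contracted band
$[0.35, 0.70]$. The amplitude of 3 mm (rather than a larger value) matters
for the same reason: steeper folds add 3D edge length on slopes, which is
spacing variance unrelated to depth.

If a drawn wave set would invert a face under the warp (strain
$\beta w < -1$ locally), the draw is rejected and retried with a
deterministically derived seed (at most 10 attempts); the uniform control
applies the same acceptance rule so folded and uniform variants of a seed
share their depth field exactly.

`make_uniform_mesh()` is the control (the analogue of templates built to
minimise spacing variability, and of the evenly spaced sphere): the same
depth field, no warp, no out-of-plane displacement, plus a tiny truncated
tessellation noise (0.2 % of the spacing). The noise amplitude is a
deliberate choice: spacing variance must be non-zero for spacing
associations to be defined at all, but the smoothing mechanism responds
deterministically to *any* spacing variance (a correlation is scale-free),
so the amplitude is set low enough that the mechanism's imprint on a
$T = 500$ local-correlation map stays well below sampling noise
($|r| \approx 0.02$, matching the statistically nil association reported
on the sphere).

What a green test on this world establishes: that the *mechanisms* —
upsampling and smoothing acting on uneven spacing — produce the reported
biases, orderings and chance levels. What it does not establish: anything
about real cortical geometry (no curvature-dependent registration, no
hemispheric structure, no vascular or neural signal), or effect *sizes* on
empirical meshes, which depend on mesh-specific spacing distributions.

## Mechanisms

`build_kernel()` constructs the geodesic Gaussian smoother:
$\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$, unnormalised weights
$\exp(-g^2/2\sigma^2)$ for geodesic distance $g$ up to the truncation
radius $r^* = \sigma\sqrt{2\ln(1/0.01)} \approx 3.03\,\sigma$ (the radius
beyond which the discarded 2D Gaussian integral fraction is 0.01 — the 2D
tail formula is a documented choice; the discrete row-sum interpretation
differs negligibly at this truncation level), then row normalisation with
the self-weight included so constants are preserved. Geodesic distances
are shortest paths along mesh edges weighted by Euclidean length
(truncated Dijkstra in compiled code), not exact polyhedral geodesics —
accurate at the 2–15 mm scales used here and swappable behind the same
interface.

`project_volume_to_surface()` implements trilinear (8-corner) and
nearest-neighbour sampling in voxel-index space through the inverse
affine, with spatial weights shared across timepoints.

## Inference

The spherical "spin test" has an exact analogue on the torus: cyclic 2D
grid translations preserve a map's autocorrelation structure while
destroying its alignment with the other map. `shift_permutation_test()`
draws random non-identity translations (or enumerates all of them),
recomputes the area-weighted correlation each time, and reports the
two-sided add-one p-value $p = (1 + \#\{|r_0| \ge |r|\})/(1 + n_{perm})$.
Its type-I error at $\alpha = 0.05$ on independent smooth maps is verified
to lie in $[0.02, 0.10]$. On non-toroidal meshes only a naive
random-vertex permutation is available; it is flagged
autocorrelation-naive in the output. Group comparisons use classical
one-sample, paired and pooled-variance two-sample t statistics; Cohen's d
uses the matching denominator (pooled SD for two samples — chosen over
Welch to match the classical d).

## Experiments and their readouts

* **E1** smoothed noise → normalised local correlation vs depth: strongly
  negative for every participant; the association with the *next*
  participant's depth is strictly weaker (individuality).
* **E2** spacing vs depth: positive, mean $\approx 0.52$.
* **E3/E4** the projection and smoothing nulls: $r(\text{spacing},
  \mathrm{lc}) < -0.5$ on folded sheets; nil on uniform sheets.
* **E5** volumetric 6-neighbour local correlation of voxel noise, projected
  to the surface: no depth association (the bias is created by surface
  processing, not present in volume data). Fisher averaging is applied to
  the volumetric statistic too, as a consistency choice.
* **E6** contiguity-constrained Ward clustering of smoothed noise: parcel
  borders sit on gyral crests (positive border-depth t for ≥ 18/20
  participants; second-level t significant); matched borders beat
  mismatched ones. Ward operates on raw time series (no rescaling), merges
  only edge-adjacent clusters, and breaks cost ties by the lowest
  representative pair so the small-instance oracle comparison is exact.
* **E7** fingerprinting: parcel-level FC of smoothed noise identifies at
  chance (5 %); within-parcel vertex-level FC identifies far above chance
  and collapses to chance once pairs closer than the largest inter-vertex
  distance are removed. Pair distances differ across participants but
  vectors must align, so a pair is dropped when it is below threshold in
  *any* participant (the cohort-minimum distance is thresholded); pairs at
  exactly the threshold are retained.
* **E8** parcel-mean bias: gyral vertices couple less with the (plain)
  parcel mean than sulcal vertices, beyond the shift null.

## Known limitations

* **E8 weighting ordering.** Empirically, area weighting *reduced* the
  parcel-mean bias magnitude. On this synthetic world the weighting offset
  is reproduced almost exactly, but it overshoots past zero
  ($|r_w| > |r_u|$), because (a) face-inversion limits the warp's strain,
  capping the sulcus-to-gyrus spacing ratio near 2.3 (empirical meshes
  reach ~3), which weakens the unweighted baseline, and (b) the smooth
  synthetic spacing field isolates gyral vertices uniformly, strengthening
  the self-weight term. The corresponding acceptance assertion is left
  failing deliberately rather than reshaping the generator after the fact.
* Wave frequencies are specified per domain, so small test sheets carry
  proportionally finer folds; all quantitative claims refer to the default
  128 mm world.
* Synthetic meshes have six neighbours per vertex; fsLR-style meshes
  mostly have five or six. The statistics do not depend on valence, but
  kernel footprints at a given FWHM differ slightly.
* The uniform control's spacing variability (CV ≈ 0.002) is far below that
  of real "uniform" templates; it is a mechanism-off control, not a
  template model.
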