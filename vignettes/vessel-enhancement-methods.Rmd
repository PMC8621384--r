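---
title: "Hybrid vessel enhancement and segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid vessel enhancement and segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselx)
```

## The problem

Retinal blood vessels are dark, curvilinear structures of varying caliber
photographed on a brighter, unevenly illuminated circular field of view.
Segmenting them pixel-by-pixel supports the assessment of diabetic
retinopathy, hypertension and other vascular pathology, but thin vessels sit
barely above the noise floor and illumination drifts across the field.
`vesselx` implements an unsupervised segmentation chain: multiscale Hessian
(Jerman) vesselness filtering, curvelet-domain contrast enhancement, local
mean-C thresholding, and morphological cleanup, evaluated by pixel
classification metrics.

## The processing model

### Green channel and aperture handling

Vessel contrast is strongest in the green channel, so all processing uses
it. The camera aperture rim is a high-contrast circular edge that would
dominate any second-derivative filter; `suppress_border()` erodes the field
of view (default 5 px) and flat-fills everything outside the eroded mask
with the mean intensity of the eroded-away rim band. The band mean rather
than the whole-field mean matters under vignette illumination: the field
center is brighter than its rim, so a whole-field fill would itself leave a
step at the boundary. When no field-of-view file is supplied, the mask is
estimated by thresholding at 10% of full scale (fundus exteriors are
near-black), keeping the largest 8-connected component and filling holes.

### Multiscale Jerman vesselness

At each scale $\sigma$ the image is convolved with Gaussian-derivative
kernels and the $\sigma^2$-normalized Hessian eigenvalues
$|\lambda_1|\le|\lambda_2|$ are computed in closed form. A dark vessel on a
bright background gives $\lambda_2 > 0$ across its section. The
larger eigenvalue is regularized per scale with cut-off $\tau$:
$$
\lambda_\rho =
\begin{cases}
\lambda_2 & \lambda_2 > \tau \max_x \lambda_2(x,\sigma) \\
\tau \max_x \lambda_2(x,\sigma) & 0 < \lambda_2 \le \tau \max_x \lambda_2 \\
0 & \text{otherwise,}
\end{cases}
$$
and the response is
$$
\nu =
\begin{cases}
0 & \lambda_2 \le 0 \lor \lambda_\rho \le 0 \\
1 & \lambda_2 \ge \lambda_\rho/2 > 0 \\
\lambda_2^2\,(\lambda_\rho-\lambda_2)\left[\frac{3}{\lambda_2+\lambda_\rho}\right]^3
  & \text{otherwise.}
\end{cases}
$$
The final map is the pointwise supremum over scales. The plateau branch is
what makes the filter attractive — the response inside a vessel of matched
scale saturates at exactly 1 regardless of its contrast — and also what
limits it (see *Known limitations*).

Defaults: $\tau = 0.5$ (lower values preserve vessel connectivity; higher
values suppress bifurcations), scales 3 to 16 px in steps of 0.5, with the
printed scale used directly as the Gaussian $\sigma$ under $\gamma = 2$
($\sigma^2$) normalization, the standard convention for this family of
filters. Polarity defaults to dark-on-bright; a switch negates both
eigenvalues for bright structures.

### Curvelet-domain enhancement

The vesselness-weighted image is decomposed by a fast discrete curvelet
transform via wrapping: unitary 2D FFT, a smooth partition of the Fourier
plane into `levels = 5` concentric coronae and angular wedges
(`angles_coarse = 16` at the second-coarsest level, doubling every second
level: 1/16/16/32 wedges plus an isotropic finest ring in the default
wavelet mode), wrapping of each windowed wedge onto a rectangular grid, and
a unitary inverse FFT per wedge. Enhancement zeroes every core-level
(s = 1) coefficient and multiplies all finer levels by `alpha = 1.2`, then
inverts the transform and min-max rescales the result to [0, 1] inside the
field of view. Removing the core darkens the smooth background; the
amplified fine levels carry the vessel edges and curvature.

Two structural properties are guaranteed by construction and verified in
the test suite: the squared analysis windows sum to one at every Fourier
grid point (a tight frame, so coefficient energy equals image energy to
machine precision) and every wedge's support lies inside its wrapped
rectangle (so the adjoint is an exact inverse; reconstruction errors are at
the 1e-14 level against the 1e-6 contract).

### Mean-C thresholding and cleanup

A pixel is vessel when it exceeds its $W \times W$ box-filter mean by more
than $C = 0.039$ on the [0, 1] intensity scale; ties are background, and
everything outside the field of view is background. $W$ defaults to 13 px
for a 565-px-wide frame and scales proportionally with image width when
left unset. The raw mask is then opened with a disk of radius 1 and
8-connected components under 30 px are dropped. Cleanup is enabled by
default but fully disableable, since removing it is also a defensible
reading of the method description; both behaviors are tested.

## Design choices that were genuinely open

**What the curvelet stage enhances.** The method description applies the
curvelet to the "Jerman-enhanced image" without defining that object. The
package default multiplies the vesselness map into the inverted green
channel (`wiring = "vesselness-times-green"`): the vesselness acts as a
tubularity gate while the inverted channel contributes the graded
photometric profile of each vessel. The alternative
(`"vesselness-only"`) feeds the raw vesselness map to the curvelet stage;
because the response saturates at 1 over wide plateaus at $\tau = 0.5$,
that map is nearly binary, the curvelet stage finds almost no ridge
structure to sharpen, and end-to-end recovery collapses — which is why it
is not the default. Both wirings remain selectable in `pipeline_config()`.

**Evaluation domain.** Metrics are computed inside the field of view by
default (the convention of the public fundus benchmarks); a switch
evaluates the whole frame.

**Per-image $\tau$.** The cut-off is a single fixed value by default.
`tau_sweep()` reports metrics across a grid of $\tau$ values per image,
making explicit how much per-image tuning moves the scores instead of
hiding it inside the pipeline.

## Numerical choices

- Derivative kernels are sampled Gaussians calibrated so constants,
  linear and quadratic inputs are differentiated exactly (zero DC, unit
  first/second moment); convolution uses reflect padding everywhere, dense
  operators on small inputs and FFT on large ones (identical to ~1e-12).
- Eigenvalues are ordered by magnitude; exact magnitude ties are ordered
  ascending by signed value.
- A per-scale maximum below 1e-10 (the floating-point residue a constant
  image leaves in the Hessian) is treated as "no structure at this scale"
  and yields a zero response.
- The min-max rescale after curvelet enhancement returns an all-zero image
  when the dynamic range is below 1e-12 (e.g. constant input).
- Thresholding uses a strict inequality; `d == C` is background.

## What the phantom generator emulates

`make_vessel_tree()` draws a seeded random binary tree of smooth curved
segments — radius tapering from parent to child — rendered as dark
Gaussian ridges on a brighter circular field with radial vignette falloff
and additive Gaussian noise; the exterior is near-black. Defaults model a
standard fundus test frame: 584 x 565 px, field-of-view radius 0.48 of the
width, vessel radii 2.5 to 6.5 px, depth 0.5 on background 0.8, vignette
amplitude 0.15, noise sd 0.01. The cross-section sigma is
$r/\sqrt{2\ln 2}$ so the truth-mask edge (distance $r$ from the
centerline) sits exactly at the profile's half-maximum — the natural
correspondence between annotated width and visible width. Typical vessel
density lands at 3–8% of the field, within the range of real fundus
annotations.

The generator deliberately omits the optic disc, fovea, lesions, central
vessel reflexes and the vessel-crossing geometry of real retinas.
Passing phantom tests therefore demonstrates correct mechanics of every
stage and realistic behavior on clean vasculature, not benchmark-grade
performance on real images — in particular, real images contain strong
non-vessel curvature (disc rim, aperture) that raises each scale's
eigenvalue maximum and thereby tempers the filter's plateau spread.

## Known limitations

- **Plateau halos bound clean-phantom recovery.** At $\tau = 0.5$ the
  plateau branch fires wherever $\lambda_2 \ge \tau\max\lambda_2/2$, which
  for a Gaussian ridge at detection scale $\sigma$ extends to roughly
  $0.9\sigma$ from the centerline. With the default scale ceiling of 16 px
  this paints a response-1 halo ~15 px wide around every
  sufficiently deep vessel, independent of its true radius. On phantoms the
  halo both adds spurious edge ridges after curvelet enhancement and raises
  the local mean under the threshold, so end-to-end Dice against the exact
  truth mask settles around 0.5–0.65 — the enhancement still beats raw
  thresholding of the green channel by a wide margin (which the test suite
  verifies), but overlap with the exact mask is capped by the halo, not by
  implementation accuracy. The effect follows analytically from the
  plateau condition and disappears as the scale ceiling approaches the
  largest vessel scale actually present.
- The curvelet wraps each wedge onto its bounding box, which for diagonal
  fine-scale wedges is larger than the sheared rectangles of the classical
  wrapping algorithm; memory, not correctness, is affected.
- GIF rasters are not read; convert dataset masks to PNG first.
- Segmentation is single-threshold; there is no hysteresis or vessel
  tracking to reconnect fragments.

## Problem sizes used by the test suite

Unit tests run on 5–128 px images with reduced scale sets; the end-to-end
phantom checks run the full default configuration on twenty 584 x 565
phantom seeds, and the reproduction script (`scripts/acceptance.R`)
recomputes its quantities on six phantom seeds plus 192–256 px analytic
fixtures. These sizes are the package's own choice of a thorough but
desk-scale battery.
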