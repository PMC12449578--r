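---
title: "Deconvolution-based cortical shell morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolution-based cortical shell morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corticon)
```

## The measurement problem

The vertebral cortical shell is a few hundred micrometres thin, while
clinical HR-QCT delivers ~0.2 mm in-plane voxels through a reconstruction
kernel whose point spread function (PSF) smears structures over a
millimetre. Any thickness measured directly on the image is therefore
dominated by blur, not anatomy. The package treats the imaging chain as a
known forward operator and estimates the underlying anatomy by fitting a
blurred model to the data, rather than by sharpening the image.

Two ideas make this tractable for the vertebral shell:

1. **Pooling.** Per-voxel or per-vertex estimates at this SNR are noise;
   instead, all voxels of the vertical cortex are pooled into nested
   radial layers (0.2 mm thick by default) by their signed distance to the
   shell mid-surface, trading topographic detail for one very stable
   density profile per vertebra.
2. **A closed-form forward model.** With a Gaussian PSF, the blurred
   profile of a piecewise-constant structure is a sum of normal CDFs, so
   the model can be evaluated exactly and fitted cheaply.

## The forward model

With the distance axis $x$ positive in the periosteal (outward) direction,
the un-blurred radial structure is modeled as: spongiosa plateau $P$ for
$x < e$; compact bone of fixed mineralization $T = 1100$ mgCaHA/cc on the
band $e \le x \le p$; soft tissue $S$ for $x > p$, with $e = c - w/2$ and
$p = c + w/2$. Gaussian blur of width $\sigma$ gives

$$\hat y(x) = S + (P - S)\,\Phi\!\left(\frac{e - x}{\sigma}\right)
  + (T - S)\left[\Phi\!\left(\frac{p - x}{\sigma}\right)
  - \Phi\!\left(\frac{e - x}{\sigma}\right)\right].$$

The limits are exact: $\hat y \to P$ deep in the spongiosa, $\hat y \to S$
outside, and as $\sigma \to 0^+$ the band indicator returns $T$ at the
mid-line. The plateau edge term is the edge spread function (ESF); the
band term is the line spread function (LSF) of the thin cortex.

Longitudinal change enters as two slabs of new matrix attached flush to
the baseline band — endosteal $[e - a_e,\, e]$ and periosteal
$[p,\, p + a_p]$ — imaged at density $f \cdot T$ where $f$ is the assumed
mineralization fraction of newly deposited matrix ($f = 0.5$ by default,
i.e. 550 mgCaHA/cc). Each slab contributes $f\,T$ times its convolved
indicator. Two consequences worth stating:

- the estimated widths scale as $1/f$ for fixed data (exactly so to first
  order in slab width over $\sigma$; the forward model is mildly nonlinear
  in $a_e, a_p$, so the package tests this property at 2% tolerance rather
  than machine precision);
- resorption is not modeled as a negative slab. Slab widths are bounded at
  zero and density loss is absorbed by the follow-up plateau, soft-tissue
  and (optionally) shell-TMD terms, which mirrors how limited resolution
  folds porosity/TMD change into the surface-zone signal.

## Fitting

`fit_baseline()` minimizes the count-weighted squared residual over
$(c, w, P, S, \sigma)$ with bounded Levenberg–Marquardt (`minpack.lm`),
$T$ fixed at 1100 mgCaHA/cc:

- **weights** per layer are the voxel counts — outer layers pool more
  voxels than inner ones;
- **initialization**: $c$ at the observed ridge, $w$ from the
  density-weighted thickness wCt.Th (a mass-based first guess), $P$/$S$
  from the profile tails, $\sigma$ at the scanner preset;
- **$\sigma$ handling**: fitted, but box-bounded to ±50% of the
  scanner-specific value. This reconciles "scanner-specific PSF" with
  "estimated during the fit": the data refine, but cannot contradict, the
  kernel's known width;
- **multistart**: three deterministic centre offsets (−1, 0, +1 layers),
  best residual wins; no random restarts, so fits are reproducible;
- **degeneracy**: a profile whose maximum sits at the domain edge, or
  whose ridge rises less than 50 mgCaHA/cc above both background levels,
  has no cortical band; the fit is flagged `DEGENERATE` rather than
  returning a meaningless width, and `dcctth()` refuses to report it.
  The 50 mgCaHA/cc margin is far below genuine band amplitudes (hundreds
  of mg/cc) and above pooled-layer noise.

`fit_apposition()` freezes the baseline geometry $(c, w, \sigma)$ — change
is modeled as a refinement of the baseline model, not a re-fit — and
estimates $(a_e, a_p, P_{fu}, S_{fu})$ on the follow-up profile extracted
in the baseline frame. `subtract_spongiosa()` removes the fitted ESF
background, leaving the band signal centred on zero in the spongiosa tail;
the subtraction stores its background so it is exactly invertible.

One pooled profile is fitted per subject; per-sector fits would
reintroduce the noise that pooling exists to remove.

## Segmentation

The package replaces template-driven active-shape segmentation (which
needs trained anatomical templates and operator interaction) with an
automated centroid-ray scheme sufficient for convex, near-elliptic
bodies: per axial slice, 180 radial profiles from the density-weighted
centroid locate the cortical ridge (global floor 200 mgCaHA/cc; a slice
whose interior runs at ridge density is classified as endplate), and each
boundary is placed at the half-height between the ridge and the local
background — soft tissue outward, trabecular plateau inward — with
sub-sample linear interpolation. A short (0.3 mm) running mean is applied
along each ray before reading the ridge, and the recovered radii are
regularized by a circular Gaussian (SD 2 angular bins). Boundary radii are
interpolated at each voxel's angle; membership is decided by voxel-centre
location with half-open comparisons, so ties cannot occur.

The vertical-cortex band trims `endplate_fraction` (default 0.15) of the
wall-slice extent at each end. The trim is anchored to wall slices rather
than the full detected body because blur smears endplate signal onto
neighbouring slices and would otherwise inflate the body height and
under-trim. Interior VOIs follow the standard layout: a 2 mm subcortical
band inward of the endosteal surface, a further 2 mm peel, and the peeled
spongiosa beyond; distances are Euclidean distances to the regularized
boundary polygon, positive outward.

## Thickness measures

`local_thickness()` implements the maximum-sphere (local thickness)
transform: each voxel is labelled with the diameter of the largest sphere
that lies entirely in the structure and contains the voxel centre. Sphere
radii are exact Euclidean distances to the background *region* — the
union of background voxel cubes, grid exterior included — not to
background voxel centres; this makes an axis-aligned 5-voxel slab at
0.2 mm spacing read exactly 1.0 mm. Candidate sphere centres are searched
on a lattice `refine` (default 3) times finer than the voxel grid, which
approaches the continuum maximum-sphere value on curved structures; odd
factors keep the original voxel centres on the candidate lattice, so
refinement can only improve the approximation. Spheres wholly contained
in a larger sphere are pruned before painting (an exact optimization),
and anisotropic spacing is handled in physical units throughout. A
"centered" variant (largest sphere centred at the voxel) is available for
sensitivity checks; it is never larger than the standard labels.

`ctth()` is the plain mean of the diameter labels over a VOI; `wctth()`
scales each label by BMD/1100 first. The rationale is mass conservation:
blur spreads the shell but preserves its mineral, so down-weighting
blurred voxels by their density recovers a first-order partial-volume
correction, while the full correction is the deconvolution fit.

## The phantom generator

`render_phantom()` builds ground truth on a grid `supersampling` (default
4) times finer than the target voxels: an elliptic-cylindrical body
(default semi-axes 10 × 7.5 mm, height 7.5 mm), a shell of fixed width at
1100 mgCaHA/cc, cortical endplate caps, and a uniform trabecular plateau —
uniformity is exactly the assumption the forward model makes, so phantom
recovery tests the estimator, not the model mismatch. An optional periodic
rod lattice (fill fraction $3p^2 - 2p^3$ for strut fraction $p$) supports
the threshold-based BV/TV and TMD tests. Partial volume at region
boundaries is handled by area-fraction weighting of signed distances; the
endosteal surface is the inward *normal offset* of the periosteal ellipse
(constant wall width everywhere) rather than a second concentric ellipse,
because a concentric ellipse does not have constant wall width and the
deconvolution targets a single true width. The geometry is deliberately
smaller than a real T12 cross-section (~35 × 25 mm): wall-local
measurements depend on the wall and the PSF, not the body size, and the
smaller body keeps a full simulated cohort tractable; all analyses used
31-phantom cohorts at these sizes.

`acquire()` applies the scanner model: separable Gaussian blur (in-plane
σ and through-plane σ, presets SIEMENS_B70S 0.39 mm / GE_BONE 0.55 mm /
PHILIPS_D 0.61 mm with 1.00 / 1.25 / 1.00 mm slice thickness), a z box
average over the slice thickness (the simplest model consistent with CT
reconstruction; the Gaussian and box z kernels are combined into one
pass), mass-conserving block-mean resampling to the target grid, and
white Gaussian noise in calibrated units (default cohort setting
25 mgCaHA/cc). The preset values 0.39/0.55/0.61 are interpreted as
Gaussian σ in mm; they are reported in the literature as "Gaussian
parameters" without units, and σ is the reading consistent with the
magnitude of the apparent-thickness inflation. Part of the final block
average is folded in ahead of the blur once every active blur scale is
sampled at ≥ 2.4 points per σ — block averaging is itself a convolution,
so the refactoring is exact for the averaging and changes the Gaussian
only at the level of kernel discretization.

What the generator does **not** emulate: posterior elements and pedicles,
beam hardening, correlated reconstruction noise, ring artifacts, helical
cone-beam geometry, in-scan motion, and real trabecular microarchitecture
(the lattice is a test pattern, not anatomy). Passing phantom tests
therefore demonstrates estimator correctness under the stated imaging
model, not robustness to everything a clinical scan can contain.

## Statistics

`summarize_changes()` computes per-subject absolute and percent change and
arm-level mean ± SD; percent change is averaged per subject, with the
ratio of arm means also reported since published tables print both
conventions consistently. `run_tests()` runs one-way ANOVA on change
scores across arms, pairwise pooled-variance Student's t-tests between
arms (Welch behind a flag), and paired t-tests within arms, flagged at
p < .05 with no multiplicity correction — matching the analysis style the
package emulates. Zero-variance inputs yield NA test rows rather than
errors; arms with fewer than two subjects are skipped with a warning.

## Numerical choices and limitations

- Gaussian kernels are built by integrating the density over each sample
  cell and truncated at 4σ; boundary taps are renormalized so constants
  are preserved. Blur + resampling conserves total mineral mass to well
  under 0.1% on phantom grids.
- Layer bins are half-open and anchored at zero; a distance of exactly
  0.31 mm falls in [0.2, 0.4).
- The ellipse signed distance uses four projection refinement steps,
  accurate to ~0.01 mm across the wall band.
- Seeds: every stochastic step (noise draws, cohort parameter draws)
  derives from an explicit integer seed and restores the caller's RNG
  state; equal seeds give byte-identical outputs.
- The half-height boundary convention places the periosteal surface
  outside the true edge by an amount that grows with σ; this is the
  expected behaviour of apparent segmentation under blur and is exactly
  what the deconvolution corrects. Consequently Ct.Th should be read as
  an apparent measure only.
- Cortical porosity is not estimable at this resolution and is not
  attempted; TMD spatial mapping and 3D thickness maps are out of scope.
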