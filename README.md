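# corticon

Deconvolution-based morphometry of the vertebral cortical shell for
high-resolution quantitative CT (HR-QCT).

## The problem

The cortical shell of a vertebral body is 200–600 μm thin — far below what
a clinical CT scanner resolves. Imaged through the scanner's point spread
function (PSF), the shell appears as a blurred band more than a millimetre
wide, so any thickness read directly off the image (`Ct.Th`, the
maximum-sphere local thickness of the segmented shell) overestimates the
true width several-fold, and cortical BMD is correspondingly diluted.
Because bone-forming therapies act on exactly this structure — adding new
matrix at the endosteal and periosteal surfaces — quantifying the shell and
its longitudinal change accurately matters for trials of osteoporosis
treatment.

`corticon` addresses this with a forward-modeling (ICON-style) approach.
All voxels around the vertical cortex are pooled into nested 200 μm radial
layers, giving a high-SNR density profile across the wall. That profile is
modeled in closed form as a Gaussian-blurred piecewise-constant structure:

- a trabecular (spongiosa) plateau `P` inside, entering as an edge spread
  function `Φ((e − x)/σ)`;
- a compact-bone band of fixed mineralization 1100 mgCaHA/cc between the
  endosteal edge `e = c − w/2` and periosteal edge `p = c + w/2`, entering
  as a line spread function `Φ((p − x)/σ) − Φ((e − x)/σ)`;
- soft tissue `S` outside.

Bounded nonlinear least squares over `(c, w, P, S, σ)` — with `σ` anchored
to the scanner-specific PSF width — yields the **deconvolved cortical
thickness** `dcCt.Th = w`, stable far below the voxel size. Longitudinal
change is fitted as two apposition slabs flush to the baseline band,
imaged at an assumed 50% mineralization of new matrix (550 mgCaHA/cc), so
the estimated widths scale as 1/f in the assumed fraction. The package
also provides density-weighted thickness (`wCt.Th` = sphere labels ×
BMD/1100), spongiosa-subtracted profiles, periosteal / central / endosteal
/ subcortical zone decomposition, cancellous BV/TV and TMD at a
250 mgCaHA/cc threshold, and arm-level ANOVA + t-test statistics.

Because trial images are not publicly deposited, the package ships a
digital vertebral phantom generator (`render_phantom()`, `acquire()`,
`make_longitudinal_pair()`, `generate_cohort()`) that emulates the imaging
chain — elliptic-cylindrical body, thin shell at 1100 mgCaHA/cc, scanner
PSFs of σ = 0.39 / 0.55 / 0.61 mm (Siemens B70s / GE BONE / Philips D),
0.2 × 0.2 × 0.3 mm voxels, 1.0–1.25 mm slice averaging, additive noise —
so every stage is testable against known ground truth.

## Worked example

Simulate one HR-QCT scan of a phantom with a 359 μm cortex on the GE
preset and measure it:

```r
library(corticon)
spec    <- phantom_spec(cortical_width_true = 359, trabecular_bmd = 115)
imaging <- imaging_spec("GE_BONE", noise_sd = 25)
truth   <- render_phantom(spec, supersampling = 4,
                          target_spacing = imaging$voxel_spacing)
scan    <- acquire(truth, imaging, seed = 7)
res     <- measure_scan(scan, scanner_sigma = imaging$psf_sigma_inplane)
res$fit
res$metrics[, c("ctth_um", "wctth_um", "dcctth_um",
                "spongiosa_bmd", "subcortex_bmd")]
```

```
<cortex_model> width 359.8 um, centre 0.061 mm, sigma 0.558 mm,
  plateau 117.7, soft tissue 0.1 mgCaHA/cc (rms 0.37, converged)
  ctth_um wctth_um dcctth_um spongiosa_bmd subcortex_bmd
1  1196.2    302.5     359.8         117.8         136.1
```

The segmentation-based `Ct.Th` reads 1196 μm — more than three times the
true width, the partial-volume inflation typical of apparent thickness —
while the density-weighted `wCt.Th` (303 μm) and especially the
deconvolved `dcCt.Th` (359.8 μm vs a true 359 μm) recover the underlying
cortex. The fitted spongiosa plateau (117.7) matches the generated
trabecular density, and the subcortical BMD is elevated by blurred-in
endplate and shell signal, as in real scans.

Longitudinal pairs work the same way through `measure_pair()`, which
freezes the baseline geometry and fits the endosteal/periosteal slab
widths; on noiseless phantoms a 50 μm apposition — a quarter of the
in-plane voxel — is recovered within a few percent.

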