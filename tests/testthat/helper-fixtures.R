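# Shared fixtures, memoized so expensive phantom simulations are built once
# per test run and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# default-geometry phantom imaged noiselessly on the GE preset, segmented
fx_ge_noiseless <- function() fixture("ge_noiseless", function() {
  spec <- phantom_spec(cortical_width_true = 359)
  im <- imaging_spec("GE_BONE", noise_sd = 0)
  truth <- render_phantom(spec, 4, im$voxel_spacing)
  vol <- acquire(truth, im, seed = 101)
  seg <- segment_cortex(vol)
  list(spec = spec, imaging = im, truth = truth, vol = vol, seg = seg)
})

# Siemens preset (sharpest PSF), noiseless - used for surface-accuracy checks
fx_siemens_noiseless <- function() fixture("siemens_noiseless", function() {
  spec <- phantom_spec(cortical_width_true = 360)
  im <- imaging_spec("SIEMENS_B70S", noise_sd = 0)
  truth <- render_phantom(spec, 4, im$voxel_spacing)
  vol <- acquire(truth, im, seed = 102)
  seg <- segment_cortex(vol)
  list(spec = spec, imaging = im, truth = truth, vol = vol, seg = seg)
})

# noiseless longitudinal pair with 50 um endosteal apposition (sub-voxel)
fx_pair_50um <- function() fixture("pair_50um", function() {
  spec <- phantom_spec(cortical_width_true = 359)
  app <- apposition_truth(endosteal_matrix = 50, mineralization_fraction = 0.5)
  im <- imaging_spec("GE_BONE", noise_sd = 0)
  make_longitudinal_pair(spec, app, im, seed = 103)
})

# analytic ellipse perimeter (numerical quadrature oracle)
ellipse_perimeter <- function(a, b) {
  stats::integrate(function(t) sqrt((a * sin(t))^2 + (b * cos(t))^2),
                   0, 2 * pi, rel.tol = 1e-10)$value
}

# synthesize a radial profile from a cortex model (optionally + apposition)
synth_profile <- function(model, apposition = NULL,
                          from = -4, to = 3, h = 0.2, counts = 500) {
  x <- seq(from + h / 2, to - h / 2, by = h)
  radial_profile(x, forward_model(model, x, apposition = apposition),
                 count = counts)
}
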