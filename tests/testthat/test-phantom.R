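test_that("phantom_spec enforces its invariants", {
  expect_error(phantom_spec(cortical_width_true = 0), "> 0")
  expect_error(phantom_spec(cortical_tmd = 100, trabecular_bmd = 200),
               ">=")
  expect_error(phantom_spec(trabecular_network = list(
    bvtv_true = 1.5, strut_spacing = 1, strut_density = 900)))
  expect_s3_class(phantom_spec(), "phantom_spec")
})

test_that("imaging presets carry the scanner PSF sigmas", {
  expect_equal(imaging_spec("SIEMENS_B70S")$psf_sigma_inplane, 0.39)
  expect_equal(imaging_spec("PHILIPS_D")$psf_sigma_inplane, 0.61)
  expect_equal(imaging_spec("GE_BONE")$psf_sigma_inplane, 0.55)
  expect_equal(imaging_spec("GE_BONE")$slice_thickness, 1.25)
  expect_error(imaging_spec("GE_BONE", noise_sd = -1), ">= 0")
  expect_error(imaging_spec("CUSTOM"), "psf_sigma_inplane")
})

test_that("rendered phantom is piecewise-constant with the right densities", {
  spec <- phantom_spec(outer_semi_axes = c(10, 7.5),
                       cortical_width_true = 360, cortical_tmd = 1100,
                       trabecular_bmd = 100, endplate_width = 0)
  truth <- render_phantom(spec, supersampling = 2)
  zs <- voxel_coords(truth, 3)
  k <- which.min(abs(zs))
  xs <- voxel_coords(truth, 1)
  ys <- voxel_coords(truth, 2)
  j0 <- which.min(abs(ys))
  # shell mid-band along +x: periosteal edge at x = 10, wall [9.64, 10]
  i_mid <- which.min(abs(xs - 9.82))
  expect_equal(truth$values[i_mid, j0, k], 1100)
  # body centre is trabecular plateau
  expect_equal(truth$values[which.min(abs(xs)), j0, k], 100)
  # far outside is background
  expect_equal(truth$values[1, 1, k], 0)
})

test_that("render rejects widths below the supersampled grid resolution", {
  expect_error(render_phantom(phantom_spec(cortical_width_true = 10),
                              supersampling = 1),
               "resolution")
})

test_that("cross-section mean density matches the analytic area mix", {
  spec <- phantom_spec(outer_semi_axes = c(10, 7.5),
                       cortical_width_true = 360, trabecular_bmd = 100,
                       endplate_width = 0)
  truth <- render_phantom(spec, 4)
  zs <- voxel_coords(truth, 3)
  V <- truth$values[, , which.min(abs(zs))]
  A <- pi * 10 * 7.5
  # wall band = inward offset of width w: area P*w - pi*w^2
  P <- ellipse_perimeter(10, 7.5)
  w <- 0.36
  Aw <- P * w - pi * w^2
  mean_analytic <- (1100 * Aw + 100 * (A - Aw)) / A
  mean_measured <- sum(V) * prod(truth$spacing[1:2]) / A
  expect_lt(abs(mean_measured / mean_analytic - 1), 0.005)
})

test_that("acquisition with no blur, matched grids and no noise is identity", {
  spec <- phantom_spec(body_height = 3, outer_semi_axes = c(5, 4))
  truth <- render_phantom(spec, supersampling = 1)
  im <- imaging_spec("CUSTOM", psf_sigma_inplane = 0,
                     voxel_spacing = truth$spacing,
                     slice_thickness = truth$spacing[3], noise_sd = 0)
  out <- acquire(truth, im, seed = 1)
  expect_equal(out$values, truth$values)
})

test_that("a uniform field stays uniform under any blur", {
  u <- voxel_volume(array(137, c(24, 24, 24)), rep(0.1, 3))
  im <- imaging_spec("CUSTOM", psf_sigma_inplane = 0.5,
                     voxel_spacing = c(0.2, 0.2, 0.2),
                     slice_thickness = 0.7, noise_sd = 0)
  out <- acquire(u, im, seed = 1)
  expect_equal(max(abs(out$values - 137)), 0, tolerance = 1e-10)
})

test_that("blur + slice averaging + resampling conserves mineral mass", {
  fx <- fx_ge_noiseless()
  rel <- abs(total_mass(fx$vol) / total_mass(fx$truth) - 1)
  expect_lt(rel, 0.001)
})

test_that("acquisition noise is reproducible and seed-controlled", {
  fx <- fx_ge_noiseless()
  im <- imaging_spec("GE_BONE", noise_sd = 25)
  a1 <- acquire(fx$truth, im, seed = 9)
  a2 <- acquire(fx$truth, im, seed = 9)
  a3 <- acquire(fx$truth, im, seed = 10)
  expect_identical(a1$values, a2$values)
  expect_false(identical(a1$values, a3$values))
})

test_that("zero apposition with no noise gives identical time points", {
  spec <- phantom_spec(outer_semi_axes = c(6, 5), body_height = 4)
  im <- imaging_spec("GE_BONE", noise_sd = 0)
  pair <- make_longitudinal_pair(spec, apposition_truth(0, 0), im, seed = 4,
                                 supersampling = 2)
  expect_equal(pair$followup$values, pair$baseline$values)
})

test_that("apposition slab adds mass at the new-matrix density", {
  spec <- phantom_spec(outer_semi_axes = c(10, 7.5), body_height = 7.5,
                       cortical_width_true = 360, endplate_width = 0.4)
  app <- apposition_truth(endosteal_matrix = 200,
                          mineralization_fraction = 0.5)
  im <- imaging_spec("GE_BONE", noise_sd = 0)
  pair <- make_longitudinal_pair(spec, app, im, seed = 4, supersampling = 2)
  dm <- total_mass(pair$followup_truth) - total_mass(pair$baseline_truth)
  # analytic slab volume: offset band between depths w and w + a of the
  # periosteal ellipse, times the core (non-endplate) height
  w <- 0.36; a <- 0.2
  P <- ellipse_perimeter(10, 7.5)
  band_area <- function(t1, t2) P * (t2 - t1) - pi * (t2^2 - t1^2)
  slab_cc <- band_area(w, w + a) * (7.5 - 2 * 0.4) / 1000
  expect_equal(dm, 550 * slab_cc, tolerance = 0.01)
})

test_that("apposition that fills the marrow cavity is rejected", {
  spec <- phantom_spec(outer_semi_axes = c(4, 3), cortical_width_true = 400)
  app <- apposition_truth(endosteal_matrix = 3000)
  expect_error(render_phantom(spec, 2, apposition = app), "marrow")
})

test_that("truth records round-trip through JSON unchanged", {
  spec <- phantom_spec(outer_semi_axes = c(6, 5), body_height = 4)
  im <- imaging_spec("GE_BONE", noise_sd = 5)
  pair <- make_longitudinal_pair(spec, apposition_truth(120, 30), im,
                                 seed = 12, supersampling = 2)
  path <- tempfile(fileext = ".json")
  write_truth_record(pair$truth_record, path)
  rec <- read_truth_record(path)
  expect_equal(rec$apposition$endosteal_matrix, 120)
  expect_equal(rec$phantom$cortical_width_true,
               pair$truth_record$phantom$cortical_width_true)
  expect_equal(rec$noise_seeds, pair$truth_record$noise_seeds)
  unlink(path)
})

test_that("cohort generation is deterministic and respects arm parameters", {
  arms <- list(
    list(name = "treated", n = 5, width_mean = 360, width_sd = 40,
         trabecular_mean = 110, trabecular_sd = 20,
         endo_mean = 130, endo_sd = 40, peri_mean = 60, peri_sd = 30),
    list(name = "placebo", n = 3, width_mean = 360, width_sd = 0,
         trabecular_mean = 110, trabecular_sd = 0,
         endo_mean = 10, endo_sd = 0, peri_mean = 5, peri_sd = 0))
  mix <- list(list(imaging = imaging_spec("GE_BONE", noise_sd = 25),
                   count = 6),
              list(imaging = imaging_spec("PHILIPS_D", noise_sd = 25),
                   count = 2))
  c1 <- generate_cohort(arms, mix, seed = 77)
  c2 <- generate_cohort(arms, mix, seed = 77)
  expect_identical(c1$truth, c2$truth)
  # sd = 0 arm: all subjects share identical truth parameters
  pl <- c1$truth[c1$truth$arm == "placebo", ]
  expect_equal(length(unique(pl$width_true_um)), 1L)
  expect_equal(unique(pl$endo_um), 10)
  # scanner mix respected
  expect_equal(sum(c1$truth$scanner == "PHILIPS_D"), 2L)
  expect_error(generate_cohort(arms, mix[1], seed = 1), "sum")
  arms_bad <- arms; arms_bad[[1]]$n <- 0
  expect_error(generate_cohort(arms_bad, mix, seed = 1), "> 0")
})

test_that("drawn cohort parameters match their distribution at large n", {
  arms <- list(list(name = "a", n = 200, width_mean = 360, width_sd = 45,
                    trabecular_mean = 115, trabecular_sd = 15,
                    endo_mean = 120, endo_sd = 40,
                    peri_mean = 60, peri_sd = 25))
  mix <- list(list(imaging = imaging_spec("GE_BONE"), count = 200))
  co <- generate_cohort(arms, mix, seed = 5)
  se <- 45 / sqrt(200)
  expect_lt(abs(mean(co$truth$width_true_um) - 360), 3 * se)
})
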