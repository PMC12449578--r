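test_that("forward model hits its analytic limits", {
  m <- cortex_model(center = 0, width = 0.36, sigma = 1e-6,
                    plateau = 100, soft_tissue = 10)
  # vanishing blur: the band indicator at its centre is the reference TMD
  expect_equal(forward_model(m, 0), 1100)
  m2 <- cortex_model(center = 0, width = 0.36, sigma = 0.55,
                     plateau = 100, soft_tissue = 10)
  expect_equal(forward_model(m2, 50), 10, tolerance = 1e-9)   # x -> +Inf: S
  expect_equal(forward_model(m2, -50), 100, tolerance = 1e-9) # x -> -Inf: P
})

test_that("closed form matches brute-force numerical convolution", {
  sigma <- 0.55
  w <- 0.359
  P <- 120; S <- 15
  m <- cortex_model(center = 0.1, width = w, sigma = sigma,
                    plateau = P, soft_tissue = S)
  app <- apposition_model(a_e = 0.15, a_p = 0.06,
                          mineralization_fraction = 0.5)
  # oracle: sample the un-blurred piecewise profile finely, convolve with a
  # sampled Gaussian kernel
  hh <- 0.001
  xg <- seq(-15, 15, by = hh)
  e <- 0.1 - w / 2; p <- 0.1 + w / 2
  f <- ifelse(xg < e, P, ifelse(xg <= p, 1100, S))
  f <- f + 550 * (xg >= e - app$a_e & xg < e) +
    550 * (xg > p & xg <= p + app$a_p)
  kern <- dnorm(seq(-6 * sigma, 6 * sigma, by = hh), sd = sigma)
  kern <- kern / sum(kern)
  blur <- stats::filter(f, kern, sides = 2)
  xq <- seq(-3, 3, by = 0.37)
  idx <- round((xq - xg[1]) / hh) + 1
  pred <- forward_model(m, xg[idx], apposition = app)
  expect_lt(max(abs(pred - as.numeric(blur[idx]))), 1e-6 * 1100)
})

test_that("baseline fit recovers the generating width on noiseless profiles", {
  truth <- cortex_model(center = 0.05, width = 0.359, sigma = 0.55,
                        plateau = 100, soft_tissue = 0)
  prof <- synth_profile(truth)
  fit <- fit_baseline(prof, init_width = 0.3, scanner_sigma = 0.55)
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  expect_lt(abs(fit$width / 0.359 - 1), 0.01)
  expect_lt(abs(fit$sigma - 0.55), 0.03)
  expect_lt(abs(fit$plateau - 100), 3)
})

test_that("the optimizer beats a full (width, centre) grid scan", {
  truth <- cortex_model(center = 0, width = 0.4, sigma = 0.5,
                        plateau = 120, soft_tissue = 5)
  prof <- synth_profile(truth)
  set.seed(2)
  prof$mean_bmd <- prof$mean_bmd + rnorm(nrow(prof), 0, 3)
  fit <- fit_baseline(prof, init_width = 0.35, scanner_sigma = 0.5)
  obj <- function(w, cc) {
    m <- cortex_model(cc, w, fit$sigma, fit$plateau, fit$soft_tissue)
    sum(prof$count * (prof$mean_bmd - forward_model(m, prof$bin_center))^2)
  }
  obj_fit <- obj(fit$width, fit$center)
  grid <- expand.grid(w = seq(0.05, 1.5, length.out = 50),
                      cc = seq(-1, 1, length.out = 50))
  obj_grid <- mapply(obj, grid$w, grid$cc)
  expect_lte(obj_fit, min(obj_grid) + 1e-9)
})

test_that("a pure plateau profile is flagged degenerate", {
  flat <- cortex_model(center = 0, width = 1e-4, sigma = 0.55,
                       plateau = 120, soft_tissue = 0)
  prof <- synth_profile(flat)
  fit <- fit_baseline(prof, init_width = 0.3, scanner_sigma = 0.55)
  expect_true(fit$degenerate)
  expect_error(dcctth(fit), "degenerate")
})

test_that("spongiosa subtraction is exact and invertible", {
  m <- cortex_model(center = 0, width = 0.36, sigma = 0.5,
                    plateau = 110, soft_tissue = 5)
  x <- seq(-3.9, 2.9, by = 0.2)
  # profile exactly equal to the ESF background -> residual identically 0
  bgprof <- radial_profile(x, esf_background(m, x), count = 10)
  resid <- subtract_spongiosa(bgprof, m)
  expect_equal(max(abs(resid$mean_bmd)), 0, tolerance = 1e-12)

  full <- synth_profile(m)
  sub <- subtract_spongiosa(full, m)
  back <- sub$mean_bmd + attr(sub, "esf_background")
  expect_equal(back, full$mean_bmd, tolerance = 1e-12)
})

test_that("spongiosa-side residual tail is centred on zero under noise", {
  m <- cortex_model(center = 0, width = 0.36, sigma = 0.5,
                    plateau = 110, soft_tissue = 0)
  x <- seq(-3.9, 2.9, by = 0.2)
  e <- m$center - m$width / 2
  set.seed(11)
  reps <- 40
  tail_means <- replicate(reps, {
    y <- forward_model(m, x) + rnorm(length(x), 0, 5)
    prof <- radial_profile(x, y, count = 400)
    fit <- fit_baseline(prof, init_width = 0.3, scanner_sigma = 0.5)
    r <- subtract_spongiosa(prof, fit)
    sel <- x < e - 3 * fit$sigma
    mean(r$mean_bmd[sel])
  })
  n_tail <- sum(x < e - 3 * 0.5)
  se <- 5 / sqrt(n_tail * reps)
  expect_lt(abs(mean(tail_means)), 4 * se)
})

test_that("apposition fit returns zero change for an unchanged profile", {
  base <- cortex_model(center = 0, width = 0.36, sigma = 0.55,
                       plateau = 100, soft_tissue = 0)
  prof <- synth_profile(base)
  fit <- fit_baseline(prof, init_width = 0.3, scanner_sigma = 0.55)
  app <- fit_apposition(fit, prof, f = 0.5)
  expect_lt(app$a_e, 1e-4)
  expect_lt(app$a_p, 1e-4)
})

test_that("apposition round-trips on noiseless synthetic follow-ups", {
  base <- cortex_model(center = 0, width = 0.36, sigma = 0.55,
                       plateau = 100, soft_tissue = 0)
  prof_b <- synth_profile(base)
  fit_b <- fit_baseline(prof_b, init_width = 0.3, scanner_sigma = 0.55)
  truth_app <- apposition_model(a_e = 0.2, a_p = 0,
                                mineralization_fraction = 0.5)
  prof_f <- synth_profile(base, apposition = truth_app)
  est <- fit_apposition(fit_b, prof_f, f = 0.5)
  expect_lt(abs(est$a_e / 0.2 - 1), 0.02)
  expect_lt(est$a_p, 0.01)
})

test_that("estimated apposition scales as 1/f in the mineralization fraction", {
  base <- cortex_model(center = 0, width = 0.36, sigma = 0.55,
                       plateau = 100, soft_tissue = 0)
  prof_b <- synth_profile(base)
  fit_b <- fit_baseline(prof_b, init_width = 0.3, scanner_sigma = 0.55)
  truth_app <- apposition_model(a_e = 0.13, a_p = 0.06,
                                mineralization_fraction = 0.5)
  prof_f <- synth_profile(base, apposition = truth_app)
  est_half <- fit_apposition(fit_b, prof_f, f = 0.5)
  est_full <- fit_apposition(fit_b, prof_f, f = 1.0)
  # fully mineralized matrix halves the estimated widths
  expect_equal(est_half$delta_w / est_full$delta_w, 2, tolerance = 0.02)
})

test_that("recovered width is robust to modest PSF misspecification", {
  for (sigma in c(0.39, 0.55, 0.61)) {
    truth <- cortex_model(center = 0, width = 0.359, sigma = sigma,
                          plateau = 100, soft_tissue = 0)
    prof <- synth_profile(truth)
    for (mis in c(0.9, 1.1)) {
      fit <- fit_baseline(prof, init_width = 0.3,
                          scanner_sigma = sigma * mis)
      expect_lt(abs(fit$width / 0.359 - 1), 0.10)
    }
  }
})

test_that("fitted band mass matches the background-subtracted integral", {
  for (sigma in c(0.39, 0.61)) {
    truth <- cortex_model(center = 0, width = 0.42, sigma = sigma,
                          plateau = 130, soft_tissue = 0)
    prof <- synth_profile(truth)
    fit <- fit_baseline(prof, init_width = 0.3, scanner_sigma = sigma)
    resid <- subtract_spongiosa(prof, fit)
    integral <- sum(resid$mean_bmd) * attr(resid, "layer_thickness")
    expect_lt(abs(integral / (fit$width * (1100 - 0)) - 1), 0.02)
  }
})

test_that("dcctth converts widths to micrometres", {
  m <- cortex_model(center = 0, width = 0.359, sigma = 0.5,
                    plateau = 100, soft_tissue = 0)
  expect_equal(dcctth(m), 359)
  # follow-up thickness: baseline width + fitted apposition
  app <- apposition_model(a_e = 0.13, a_p = 0.064)
  expect_equal(dcctth(m) + 1000 * app$delta_w, 553)
  app0 <- apposition_model(0, 0)
  expect_equal(dcctth(m) + 1000 * app0$delta_w, dcctth(m))
})

test_that("arm-mean apposition is recovered across a simulated cohort", {
  # cohort parameters drawn by the generator; profiles simulated at the
  # forward-model level with realistic layer noise, then fitted
  arms <- list(
    list(name = "romosozumab", n = 11, width_mean = 364, width_sd = 36,
         trabecular_mean = 110, trabecular_sd = 20,
         endo_mean = 129, endo_sd = 36, peri_mean = 65, peri_sd = 30),
    list(name = "teriparatide", n = 12, width_mean = 349, width_sd = 49,
         trabecular_mean = 110, trabecular_sd = 20,
         endo_mean = 47, endo_sd = 25, peri_mean = 24, peri_sd = 18),
    list(name = "placebo", n = 8, width_mean = 366, width_sd = 76,
         trabecular_mean = 110, trabecular_sd = 20,
         endo_mean = 8, endo_sd = 12, peri_mean = 4, peri_sd = 8))
  mix <- list(list(imaging = imaging_spec("SIEMENS_B70S"), count = 4),
              list(imaging = imaging_spec("GE_BONE"), count = 20),
              list(imaging = imaging_spec("PHILIPS_D"), count = 7))
  co <- generate_cohort(arms, mix, seed = 2024)
  tr <- co$truth
  set.seed(99)
  est <- vapply(seq_len(nrow(tr)), function(i) {
    base <- cortex_model(center = 0, width = tr$width_true_um[i] / 1000,
                         sigma = tr$psf_sigma[i],
                         plateau = tr$trabecular_bmd[i], soft_tissue = 0)
    prof_b <- synth_profile(base)
    prof_b$mean_bmd <- prof_b$mean_bmd + rnorm(nrow(prof_b), 0, 1.5)
    fit_b <- fit_baseline(prof_b, init_width = 0.3,
                          scanner_sigma = tr$psf_sigma[i])
    app <- apposition_model(tr$endo_um[i] / 1000, tr$peri_um[i] / 1000,
                            mineralization_fraction = 0.5)
    prof_f <- synth_profile(base, apposition = app)
    prof_f$mean_bmd <- prof_f$mean_bmd + rnorm(nrow(prof_f), 0, 1.5)
    1000 * fit_apposition(fit_b, prof_f, f = 0.5)$delta_w
  }, numeric(1))
  truth_dw <- tr$endo_um + tr$peri_um
  for (a in unique(tr$arm)) {
    sel <- tr$arm == a
    se <- sd(truth_dw[sel]) / sqrt(sum(sel))
    expect_lt(abs(mean(est[sel]) - mean(truth_dw[sel])), max(se, 2))
  }
})
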