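test_that("a 5-voxel slab at 0.2 mm spacing is labelled exactly 1.0 mm", {
  slab <- array(FALSE, c(30, 30, 13))
  slab[, , 5:9] <- TRUE
  lab <- local_thickness(slab, c(0.2, 0.2, 0.2), refine = 1)
  # away from the open lateral grid edges, every slab voxel reads 1.0 mm
  interior <- lab[4:27, 4:27, 5:9]
  expect_equal(unique(as.numeric(interior)), 1.0)
  # sub-voxel centre refinement preserves the aligned-slab exactness
  lab2 <- local_thickness(slab, c(0.2, 0.2, 0.2), refine = 3)
  expect_equal(unique(as.numeric(lab2[4:27, 4:27, 5:9])), 1.0)
  expect_error(local_thickness(slab, c(0.2, 0.2, 0.2), refine = 2), "odd")
})

test_that("a digital ball is labelled close to its diameter at the centre", {
  n <- 41
  cc <- 21
  g <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  r <- sqrt((g$i - cc)^2 + (g$j - cc)^2 + (g$k - cc)^2) * 0.2
  ball <- array(r <= 3, c(n, n, n))
  lab <- local_thickness(ball, c(0.2, 0.2, 0.2), refine = 1)
  expect_lt(abs(lab[cc, cc, cc] - 6), 2 * 0.2)
})

test_that("labels match an exhaustive sphere-search oracle on random masks", {
  set.seed(14)
  dims <- c(20, 20, 20)
  sp <- c(0.2, 0.2, 0.3)
  # random blobby mask: threshold smoothed noise
  raw <- array(rnorm(prod(dims)), dims)
  sm <- raw
  for (ax in 1:3) {
    k <- c(1, 2, 3, 2, 1); k <- k / sum(k)
    sm <- corticon:::cc_conv_axis(as.numeric(sm), dims, k, ax - 1L)
    dim(sm) <- dims
  }
  mask <- sm > 0.1
  mask[1, , ] <- FALSE  # keep some background
  expect_gt(sum(mask), 100)

  lab <- local_thickness(mask, sp, refine = 1)

  # oracle: enumerate all candidate centres; radius = exact distance to the
  # background region (union of background voxel cubes, grid exterior
  # included); label = max diameter over spheres containing the voxel
  idx <- which(mask | !mask, arr.ind = TRUE)  # all voxels
  pos <- cbind(idx[, 1] * sp[1], idx[, 2] * sp[2], idx[, 3] * sp[3])
  is_fg <- as.logical(mask)
  half <- sp / 2
  # background positions: background voxels plus a one-voxel exterior rind
  ext <- expand.grid(i = 0:(dims[1] + 1), j = 0:(dims[2] + 1),
                     k = 0:(dims[3] + 1))
  inside_grid <- ext$i >= 1 & ext$i <= dims[1] & ext$j >= 1 &
    ext$j <= dims[2] & ext$k >= 1 & ext$k <= dims[3]
  bg_keep <- !inside_grid
  bg_keep[inside_grid] <- !is_fg
  bgp <- cbind(ext$i[bg_keep] * sp[1], ext$j[bg_keep] * sp[2],
               ext$k[bg_keep] * sp[3])
  fgp <- pos[is_fg, , drop = FALSE]
  nf <- nrow(fgp)
  rad <- numeric(nf)
  for (t in seq_len(nf)) {
    dx <- pmax(abs(bgp[, 1] - fgp[t, 1]) - half[1], 0)
    dy <- pmax(abs(bgp[, 2] - fgp[t, 2]) - half[2], 0)
    dz <- pmax(abs(bgp[, 3] - fgp[t, 3]) - half[3], 0)
    rad[t] <- sqrt(min(dx^2 + dy^2 + dz^2))
  }
  oracle <- numeric(nf)
  for (t in seq_len(nf)) {
    dd <- sqrt((fgp[, 1] - fgp[t, 1])^2 + (fgp[, 2] - fgp[t, 2])^2 +
               (fgp[, 3] - fgp[t, 3])^2)
    oracle[t] <- 2 * max(rad[dd <= rad + 1e-12])
  }
  expect_equal(lab[mask], oracle, tolerance = 1e-12)
})

test_that("mean thickness reductions behave like plain averages", {
  lab <- array(0, c(4, 4, 4))
  voi <- array(FALSE, c(4, 4, 4))
  lab[1:2, , ] <- 0.8
  lab[3:4, , ] <- 2.4
  voi[1:4, , ] <- TRUE
  expect_equal(ctth(lab, voi), 1600)  # mean of 0.8 and 2.4 mm in um
  voi2 <- voi; voi2[3:4, , ] <- FALSE
  expect_equal(ctth(lab, voi2), 800)
  set.seed(3)
  lab[] <- runif(64, 0.1, 2)
  expect_equal(ctth(lab, voi), mean(lab) * 1000, tolerance = 1e-12)
  expect_error(ctth(lab, array(FALSE, c(4, 4, 4))), "empty")
})

test_that("density weighting scales thickness by BMD over 1100", {
  lab <- array(1.2, c(4, 4, 4))
  voi <- array(TRUE, c(4, 4, 4))
  mk <- function(val) voxel_volume(array(val, c(4, 4, 4)), c(0.2, 0.2, 0.2))
  expect_equal(wctth(lab, mk(1100), voi), ctth(lab, voi))
  expect_equal(wctth(lab, mk(550), voi), ctth(lab, voi) / 2)
  set.seed(8)
  vals <- array(runif(64, 100, 1100), c(4, 4, 4))
  v <- voxel_volume(vals, c(0.2, 0.2, 0.2))
  expect_equal(wctth(lab, v, voi),
               mean(1.2 * vals / 1100) * 1000, tolerance = 1e-12)
  # scaling BMD by k scales wctth by exactly k
  v2 <- voxel_volume(vals * 0.7, c(0.2, 0.2, 0.2))
  expect_equal(wctth(lab, v2, voi), 0.7 * wctth(lab, v, voi),
               tolerance = 1e-12)
})

test_that("blurred shells overestimate Ct.Th while wCt.Th self-corrects", {
  fx <- fx_ge_noiseless()
  vert <- vertical_cortex_only(fx$seg)
  lab <- local_thickness(fx$seg$cortical_mask, fx$vol$spacing)
  ct <- ctth(lab, vert)
  wct <- wctth(lab, fx$vol, vert)
  true_w <- fx$spec$cortical_width_true
  expect_gt(ct, 2 * true_w)             # strong partial-volume inflation
  expect_lt(abs(wct / true_w - 1), 0.25) # mass-based correction
  expect_lt(wct, ct)
})

test_that("the centered-sphere variant never exceeds the containing labels", {
  slab <- array(FALSE, c(20, 20, 9))
  slab[, , 3:7] <- TRUE
  lab_c <- local_thickness(slab, c(0.2, 0.2, 0.2), method = "centered")
  lab_s <- local_thickness(slab, c(0.2, 0.2, 0.2), refine = 1)
  expect_true(all(lab_c <= lab_s + 1e-12))
})
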