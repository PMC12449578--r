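#' Vertebral phantom specification
#'
#' Describes a ground-truth digital vertebral body: an elliptic-cylindrical
#' body with a thin cortical shell of fixed tissue mineral density over a
#' trabecular interior, capped by endplates. The shell occupies the band
#' between the periosteal ellipse and its inward normal offset, so the wall
#' has constant true width everywhere.
#'
#' @param outer_semi_axes length-2, periosteal ellipse semi-axes (mm).
#' @param body_height cranio-caudal extent of the body (mm).
#' @param cortical_width_true true cortical width in micrometres.
#' @param cortical_tmd shell tissue mineral density, mgCaHA/cc.
#' @param trabecular_bmd uniform trabecular plateau density, mgCaHA/cc.
#'   Ignored when `trabecular_network` is given.
#' @param trabecular_network optional list with `bvtv_true` (target bone
#'   volume fraction, 0..1), `strut_spacing` (mm) and `strut_density`
#'   (mgCaHA/cc) describing a periodic rod lattice replacing the uniform
#'   plateau.
#' @param background_bmd density outside the body, mgCaHA/cc.
#' @param endplate_width thickness of the cortical endplate caps, mm.
#' @param seed integer; reserved for stochastic interior models.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(outer_semi_axes = c(10, 7.5),
                         body_height = 7.5,
                         cortical_width_true = 360,
                         cortical_tmd = 1100,
                         trabecular_bmd = 115,
                         trabecular_network = NULL,
                         background_bmd = 0,
                         endplate_width = 0.4,
                         seed = 1L) {
  stopifnot(length(outer_semi_axes) == 2L, all(outer_semi_axes > 0),
            body_height > 0, endplate_width >= 0)
  if (!is.finite(cortical_width_true) || cortical_width_true <= 0)
    stop("cortical_width_true must be > 0 (micrometres)")
  plateau <- if (is.null(trabecular_network)) trabecular_bmd else {
    stopifnot(is.list(trabecular_network),
              trabecular_network$bvtv_true >= 0,
              trabecular_network$bvtv_true <= 1,
              trabecular_network$strut_spacing > 0)
    trabecular_network$bvtv_true * trabecular_network$strut_density
  }
  if (cortical_tmd < plateau)
    stop("cortical_tmd must be >= the trabecular plateau density")
  structure(
    list(outer_semi_axes = as.numeric(outer_semi_axes),
         body_height = body_height,
         cortical_width_true = cortical_width_true,
         cortical_tmd = cortical_tmd,
         trabecular_bmd = trabecular_bmd,
         trabecular_network = trabecular_network,
         background_bmd = background_bmd,
         endplate_width = endplate_width,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' HR-QCT imaging specification
#'
#' Scanner presets carry the reconstruction-kernel-specific Gaussian PSF
#' width (sigma, mm) and slice thickness: `SIEMENS_B70S` sigma 0.39 / slice
#' 1.00 mm, `PHILIPS_D` sigma 0.61 / slice 1.00 mm, `GE_BONE` sigma 0.55 /
#' slice 1.25 mm. Use `CUSTOM` to set everything explicitly.
#'
#' @param scanner_preset one of `"SIEMENS_B70S"`, `"PHILIPS_D"`, `"GE_BONE"`,
#'   `"CUSTOM"`.
#' @param psf_sigma_inplane in-plane Gaussian PSF sigma, mm (0 = no blur).
#' @param psf_sigma_z through-plane PSF sigma, mm; defaults to the in-plane
#'   value.
#' @param voxel_spacing target grid spacing, mm (x, y, z).
#' @param slice_thickness z box-averaging width, mm.
#' @param noise_sd additive white Gaussian noise SD, mgCaHA/cc.
#' @return object of class `imaging_spec`.
#' @export
imaging_spec <- function(scanner_preset = c("GE_BONE", "SIEMENS_B70S",
                                            "PHILIPS_D", "CUSTOM"),
                         psf_sigma_inplane = NULL,
                         psf_sigma_z = NULL,
                         voxel_spacing = c(0.2, 0.2, 0.3),
                         slice_thickness = NULL,
                         noise_sd = 0) {
  scanner_preset <- match.arg(scanner_preset)
  presets <- list(
    SIEMENS_B70S = list(sigma = 0.39, slice = 1.00),
    PHILIPS_D    = list(sigma = 0.61, slice = 1.00),
    GE_BONE      = list(sigma = 0.55, slice = 1.25)
  )
  if (scanner_preset == "CUSTOM") {
    if (is.null(psf_sigma_inplane))
      stop("CUSTOM preset requires psf_sigma_inplane")
    if (is.null(slice_thickness)) slice_thickness <- voxel_spacing[3]
  } else {
    p <- presets[[scanner_preset]]
    if (is.null(psf_sigma_inplane)) psf_sigma_inplane <- p$sigma
    if (is.null(slice_thickness)) slice_thickness <- p$slice
  }
  if (is.null(psf_sigma_z)) psf_sigma_z <- psf_sigma_inplane
  stopifnot(psf_sigma_inplane >= 0, psf_sigma_z >= 0,
            length(voxel_spacing) == 3L, all(voxel_spacing > 0),
            slice_thickness > 0)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(scanner_preset = scanner_preset,
         psf_sigma_inplane = psf_sigma_inplane,
         psf_sigma_z = psf_sigma_z,
         voxel_spacing = as.numeric(voxel_spacing),
         slice_thickness = slice_thickness,
         noise_sd = noise_sd),
    class = "imaging_spec"
  )
}

#' Ground-truth longitudinal apposition
#'
#' New bone matrix added at the endosteal and/or periosteal surface between
#' baseline and follow-up, deposited at a given mineralization fraction of
#' the 1100 mgCaHA/cc reference (0.5 means the new matrix images at
#' 550 mgCaHA/cc).
#'
#' @param endosteal_matrix slab width added inside the endosteal surface,
#'   micrometres.
#' @param periosteal_matrix slab width added outside the periosteal surface,
#'   micrometres.
#' @param mineralization_fraction fraction in (0, 1].
#' @param existing_cortex_tmd_change additive density change of the original
#'   shell, mgCaHA/cc.
#' @return object of class `apposition_truth`.
#' @export
apposition_truth <- function(endosteal_matrix = 0, periosteal_matrix = 0,
                             mineralization_fraction = 0.5,
                             existing_cortex_tmd_change = 0) {
  stopifnot(endosteal_matrix >= 0, periosteal_matrix >= 0)
  if (mineralization_fraction <= 0 || mineralization_fraction > 1)
    stop("mineralization_fraction must be in (0, 1]")
  structure(
    list(endosteal_matrix = endosteal_matrix,
         periosteal_matrix = periosteal_matrix,
         mineralization_fraction = mineralization_fraction,
         existing_cortex_tmd_change = existing_cortex_tmd_change),
    class = "apposition_truth"
  )
}

# Signed distance (mm) from points (x, y) to the ellipse
# x^2/a^2 + y^2/b^2 = 1; negative inside. A first-order level-set step is
# refined by projecting towards the curve, giving near-exact distances over
# the wall-scale band around the boundary.
ellipse_signed_distance <- function(x, y, a, b) {
  px <- x; py <- y
  for (it in 1:4) {
    sf <- sqrt((px / a)^2 + (py / b)^2)
    gx <- px / a^2
    gy <- py / b^2
    gn <- sqrt(gx^2 + gy^2)
    bad <- gn <= .Machine$double.eps
    gn[bad] <- 1
    step <- (sf - 1) * sf / gn
    step[bad] <- 0
    px <- px - step * gx / gn
    py <- py - step * gy / gn
  }
  d <- sqrt((x - px)^2 + (y - py)^2)
  inside <- (x / a)^2 + (y / b)^2 < 1
  d[inside] <- -d[inside]
  # degenerate centre: distance is minus the minor semi-axis
  centre <- abs(x) <= .Machine$double.eps & abs(y) <= .Machine$double.eps
  d[centre] <- -min(a, b)
  d
}

# Coverage fraction of a pixel of width h by the half-space {d <= edge}.
coverage <- function(d, edge, h) {
  pmin(pmax(0.5 + (edge - d) / h, 0), 1)
}

#' Render a ground-truth phantom volume
#'
#' Builds the un-blurred phantom on a grid `supersampling` times finer than
#' the target voxel grid. Sub-grid partial volume at region boundaries is
#' handled by area-fraction weighting of the signed distance to each
#' interface.
#'
#' @param spec a [phantom_spec()].
#' @param supersampling integer >= 1, refinement factor per axis.
#' @param target_spacing target voxel spacing (mm), default HR-QCT
#'   0.2 x 0.2 x 0.3.
#' @param margin background margin around the body, mm.
#' @param apposition optional [apposition_truth()] to render the follow-up
#'   state.
#' @return a [voxel_volume()] on the supersampled grid.
#' @export
render_phantom <- function(spec, supersampling = 4L,
                           target_spacing = c(0.2, 0.2, 0.3),
                           margin = 2, apposition = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), supersampling >= 1)
  s <- as.integer(supersampling)
  h <- target_spacing / s
  w <- spec$cortical_width_true / 1000  # mm
  if (w < min(h[1:2]))
    stop("cortical width below one supersampled voxel; ",
         "increase supersampling (resolution error)")

  a <- spec$outer_semi_axes[1]
  b <- spec$outer_semi_axes[2]
  ae <- pe <- 0
  f_min <- 1
  dtmd <- 0
  if (!is.null(apposition)) {
    stopifnot(inherits(apposition, "apposition_truth"))
    ae <- apposition$endosteal_matrix / 1000
    pe <- apposition$periosteal_matrix / 1000
    f_min <- apposition$mineralization_fraction
    dtmd <- apposition$existing_cortex_tmd_change
    if (b - w - ae <= 0)
      stop("endosteal apposition slab fills the marrow cavity completely")
  }

  # target grid sized to hold the body plus margin (and periosteal slab);
  # the z margin is widened so PSF + slice-averaging tails of the endplates
  # decay inside the grid and blur remains mass-conserving
  ext <- c(a, b) + margin + pe
  n_t <- c(2 * ceiling(ext[1] / target_spacing[1]),
           2 * ceiling(ext[2] / target_spacing[2]),
           2 * ceiling((spec$body_height / 2 + margin + 1.5) /
                         target_spacing[3]))
  n_f <- n_t * s
  # voxel-centre coordinates, grid symmetric about the origin
  xc <- (seq_len(n_f[1]) - (n_f[1] + 1) / 2) * h[1]
  yc <- (seq_len(n_f[2]) - (n_f[2] + 1) / 2) * h[2]
  zc <- (seq_len(n_f[3]) - (n_f[3] + 1) / 2) * h[3]

  d <- ellipse_signed_distance(matrix(xc, n_f[1], n_f[2]),
                               matrix(yc, n_f[1], n_f[2], byrow = TRUE),
                               a, b)
  hp <- mean(h[1:2])  # in-plane pixel scale for coverage fractions
  f0 <- coverage(d, 0, hp)           # inside periosteal surface
  fw <- coverage(d, -w, hp)          # inside endosteal surface
  f_per <- coverage(d, pe, hp)       # inside outer edge of periosteal slab
  f_end <- coverage(d, -w - ae, hp)  # inside inner edge of endosteal slab

  tmd <- spec$cortical_tmd
  bg <- spec$background_bmd
  slab_rho <- f_min * 1100

  # wall cross-section template (everything except the trabecular interior)
  wall2d <- (tmd + dtmd) * (f0 - fw) + bg * (1 - f0) +
    slab_rho * ((f_per - f0) + (fw - f_end))
  # cap cross-section: fully cortical inside the periosteal surface
  cap2d <- tmd * f0 + bg * (1 - f0)

  half_h <- spec$body_height / 2
  epw <- min(spec$endplate_width, half_h)
  fz_body <- coverage(abs(zc), half_h, h[3])
  fz_core <- coverage(abs(zc), half_h - epw, h[3])
  fz_cap <- fz_body - fz_core

  net <- spec$trabecular_network
  vals <- array(0, dim = n_f)
  if (is.null(net)) {
    trab2d <- spec$trabecular_bmd * fw
    layer_core <- wall2d + trab2d
    for (k in seq_len(n_f[3])) {
      vals[, , k] <- fz_core[k] * layer_core + fz_cap[k] * cap2d +
        (1 - fz_body[k]) * bg
    }
  } else {
    # periodic 3-axis rod lattice: a point is bone when at least two of its
    # three lattice-fractional coordinates fall inside the strut width; the
    # continuum fill fraction is 3 p^2 - 2 p^3 with p = width/spacing.
    p <- lattice_p(net$bvtv_true)
    sp <- net$strut_spacing
    inx <- matrix((xc / sp) %% 1 < p, n_f[1], n_f[2])
    iny <- matrix((yc / sp) %% 1 < p, n_f[1], n_f[2], byrow = TRUE)
    for (k in seq_len(n_f[3])) {
      fzk <- (zc[k] / sp) %% 1 < p
      bone <- (inx & iny) | (fzk & (inx | iny))
      trab2d <- net$strut_density * bone * fw
      vals[, , k] <- fz_core[k] * (wall2d + trab2d) + fz_cap[k] * cap2d +
        (1 - fz_body[k]) * bg
    }
  }
  voxel_volume(vals, spacing = h,
               origin = c(xc[1], yc[1], zc[1]), calibrated = TRUE)
}

# Invert fill = 3 p^2 - 2 p^3 for p in [0, 1].
lattice_p <- function(fill) {
  stopifnot(fill >= 0, fill <= 1)
  if (fill == 0) return(0)
  if (fill == 1) return(1)
  stats::uniroot(function(p) 3 * p^2 - 2 * p^3 - fill, c(0, 1),
                 tol = 1e-12)$root
}

# Discretised Gaussian kernel (unit sum) for sigma and sample step h.
gaussian_kernel <- function(sigma, h) {
  if (sigma <= 0) return(1)
  hw <- max(1L, ceiling(4 * sigma / h))
  x <- (-hw):hw
  # integrate the Gaussian over each tap's cell for better small-sigma fidelity
  k <- pnorm(((x + 0.5) * h) / sigma) - pnorm(((x - 0.5) * h) / sigma)
  k / sum(k)
}

# Box kernel of physical width w sampled at step h (fractional end taps).
box_kernel <- function(w, h) {
  if (w <= h) return(1)
  hw <- ceiling((w / h - 1) / 2)
  x <- (-hw):hw
  k <- pmin((x + 0.5) * h, w / 2) - pmax((x - 0.5) * h, -w / 2)
  k <- pmax(k, 0)
  k / sum(k)
}

#' Simulate HR-QCT acquisition of a ground-truth volume
#'
#' Applies the scanner's Gaussian PSF (in-plane and z), box-averages over the
#' slice thickness along z, resamples to the target voxel grid by block
#' averaging (mass conserving), and adds white Gaussian noise in calibrated
#' units.
#'
#' @param truth a [voxel_volume()] on a grid at least as fine as the target.
#' @param imaging an [imaging_spec()].
#' @param seed integer seed for the noise draw.
#' @return a [voxel_volume()] on the target grid.
#' @export
acquire <- function(truth, imaging, seed = 1L) {
  stopifnot(inherits(truth, "voxel_volume"), inherits(imaging, "imaging_spec"))
  if (imaging$noise_sd < 0) stop("noise_sd must be >= 0")
  h <- truth$spacing
  fac <- imaging$voxel_spacing / h
  fac_i <- as.integer(round(fac))
  if (any(abs(fac - fac_i) > 1e-6) || any(fac_i < 1))
    stop("truth grid must be an integer refinement of the target grid")

  dims <- dim(truth$values)
  v <- as.numeric(truth$values)
  sig <- c(imaging$psf_sigma_inplane, imaging$psf_sigma_inplane,
           imaging$psf_sigma_z)
  # Fold part of the final block average in ahead of the blur: block
  # averaging is itself a convolution, so it commutes with the Gaussian and
  # the slice box; it may be applied early as long as every active blur
  # scale stays well sampled (>= 2.4 samples per sigma) on the coarser grid.
  while (all(fac_i %% 2L == 0L) &&
         all(sig == 0 | sig >= 2.4 * 2 * h)) {
    v <- cc_block_mean(v, dims, c(2L, 2L, 2L))
    dims <- dims %/% 2L
    origin_shift <- h / 2
    truth$origin <- truth$origin + origin_shift
    h <- 2 * h
    fac_i <- fac_i %/% 2L
    v <- as.numeric(v)
  }
  for (ax in 1:2) {
    k <- gaussian_kernel(sig[ax], h[ax])
    if (length(k) > 1)
      v <- cc_conv_axis(v, dims, k, ax - 1L)
  }
  # single z pass: Gaussian PSF and slice box-average kernels combined
  kgz <- gaussian_kernel(sig[3], h[3])
  kbz <- box_kernel(imaging$slice_thickness, h[3])
  kz <- if (length(kgz) == 1) kbz else if (length(kbz) == 1) kgz else
    convolve(kgz, rev(kbz), type = "open")  # full convolution, odd length
  if (length(kz) > 1)
    v <- cc_conv_axis(v, dims, kz / sum(kz), 2L)

  if (any(fac_i > 1)) {
    pad <- dims %% fac_i
    if (any(pad != 0)) stop("truth grid dims not divisible by resampling factor")
    v <- cc_block_mean(v, dims, fac_i)
  } else {
    dim(v) <- dims
  }
  out_dim <- dims %/% fac_i
  origin <- truth$origin + (fac_i - 1) / 2 * h

  if (imaging$noise_sd > 0) {
    v <- v + with_seed(seed, rnorm(length(v), 0, imaging$noise_sd))
  }
  dim(v) <- out_dim
  voxel_volume(v, spacing = imaging$voxel_spacing, origin = origin,
               calibrated = truth$calibrated)
}

# Evaluate `expr` under a temporary RNG state; restores the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a baseline / follow-up phantom pair with known apposition
#'
#' The follow-up truth adds slabs of density
#' `mineralization_fraction * 1100` mgCaHA/cc flush to the endosteal and
#' periosteal surfaces and applies any TMD change to the original shell;
#' both time points are then imaged with independent noise draws.
#'
#' @param spec a [phantom_spec()].
#' @param apposition an [apposition_truth()].
#' @param imaging an [imaging_spec()].
#' @param seed integer controlling both noise draws.
#' @param supersampling,margin forwarded to [render_phantom()].
#' @return list with `baseline`, `followup` (target-grid [voxel_volume()]s),
#'   `truth_record` (all ground-truth parameters), and the un-blurred
#'   `baseline_truth` / `followup_truth` volumes.
#' @export
make_longitudinal_pair <- function(spec, apposition, imaging, seed = 1L,
                                   supersampling = 4L, margin = 2) {
  stopifnot(inherits(apposition, "apposition_truth"))
  # pad the baseline grid by the periosteal slab width so both time points
  # share one grid
  pad <- apposition$periosteal_matrix / 1000
  tb <- render_phantom(spec, supersampling, imaging$voxel_spacing,
                       margin + pad)
  tf <- render_phantom(spec, supersampling, imaging$voxel_spacing, margin,
                       apposition = apposition)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L))
  base <- acquire(tb, imaging, seeds[1])
  foll <- acquire(tf, imaging, seeds[2])
  truth_record <- list(
    phantom = unclass(spec)[setdiff(names(spec), "trabecular_network")],
    trabecular_network = spec$trabecular_network,
    apposition = unclass(apposition),
    imaging = unclass(imaging),
    seed = as.integer(seed),
    noise_seeds = as.integer(seeds)
  )
  list(baseline = base, followup = foll, truth_record = truth_record,
       baseline_truth = tb, followup_truth = tf)
}

#' Write / read a ground-truth record
#'
#' @param record truth record from [make_longitudinal_pair()].
#' @param path JSON file path.
#' @return `read_truth_record` returns the record; `write_truth_record`
#'   returns `path` invisibly.
#' @export
write_truth_record <- function(record, path) {
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth_record
#' @export
read_truth_record <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# Truncated-normal draw by rejection (deterministic under the current seed).
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

#' Generate a longitudinal phantom cohort
#'
#' Draws per-subject ground-truth parameters from arm-level normal
#' distributions (truncated at physiologic bounds), assigns scanners
#' according to the imaging mix, and returns reproducible subject bundles
#' plus a ground-truth table. Volumes are rendered lazily per subject with
#' [simulate_subject()] to keep memory bounded.
#'
#' @param arm_specs list of arms, each a list with `name`, `n`, `width_mean`,
#'   `width_sd` (baseline cortical width, micrometres), `trabecular_mean`,
#'   `trabecular_sd` (mgCaHA/cc), `endo_mean`, `endo_sd`, `peri_mean`,
#'   `peri_sd` (apposition per surface, micrometres).
#' @param imaging_mix list of `list(imaging = imaging_spec, count = n)`;
#'   counts must sum to the total cohort size.
#' @param seed integer master seed.
#' @param mineralization_fraction fraction for the new matrix (default 0.5).
#' @param base_spec template [phantom_spec()] supplying geometry defaults.
#' @return object of class `phantom_cohort`: list with `truth`
#'   (data.frame, one row per subject) and `subjects` (parameter bundles).
#' @export
generate_cohort <- function(arm_specs, imaging_mix, seed = 1L,
                            mineralization_fraction = 0.5,
                            base_spec = phantom_spec()) {
  for (a in arm_specs) {
    if (is.null(a$n) || a$n <= 0) stop("arm size n must be > 0")
  }
  counts <- vapply(imaging_mix, function(m) as.integer(m$count), integer(1))
  n_total <- sum(vapply(arm_specs, function(a) as.integer(a$n), integer(1)))
  if (sum(counts) != n_total)
    stop("imaging_mix counts must sum to the total cohort size")

  with_seed(seed, {
    scanner_idx <- sample(rep(seq_along(imaging_mix), counts))
    rows <- list()
    subjects <- list()
    sid <- 0L
    for (a in arm_specs) {
      widths <- rtrunc_norm(a$n, a$width_mean, a$width_sd, 150, 800)
      trabs <- rtrunc_norm(a$n, a$trabecular_mean, a$trabecular_sd, 20, 300)
      endos <- rtrunc_norm(a$n, a$endo_mean, a$endo_sd, 0, Inf)
      peris <- rtrunc_norm(a$n, a$peri_mean, a$peri_sd, 0, Inf)
      subj_seeds <- sample.int(.Machine$integer.max - 1L, a$n)
      for (i in seq_len(a$n)) {
        sid <- sid + 1L
        im <- imaging_mix[[scanner_idx[sid]]]$imaging
        rows[[sid]] <- data.frame(
          subject = sid, arm = a$name,
          scanner = im$scanner_preset,
          psf_sigma = im$psf_sigma_inplane,
          width_true_um = widths[i],
          trabecular_bmd = trabs[i],
          endo_um = endos[i], peri_um = peris[i],
          mineralization_fraction = mineralization_fraction,
          seed = subj_seeds[i],
          stringsAsFactors = FALSE)
        subjects[[sid]] <- list(
          subject = sid, arm = a$name, imaging = im,
          spec = phantom_spec(
            outer_semi_axes = base_spec$outer_semi_axes,
            body_height = base_spec$body_height,
            cortical_width_true = widths[i],
            cortical_tmd = base_spec$cortical_tmd,
            trabecular_bmd = trabs[i],
            background_bmd = base_spec$background_bmd,
            endplate_width = base_spec$endplate_width,
            seed = subj_seeds[i]),
          apposition = apposition_truth(
            endosteal_matrix = endos[i], periosteal_matrix = peris[i],
            mineralization_fraction = mineralization_fraction),
          seed = subj_seeds[i])
      }
    }
    structure(list(truth = do.call(rbind, rows), subjects = subjects),
              class = "phantom_cohort")
  })
}

#' Realise one cohort subject as imaged volumes
#'
#' @param cohort a `phantom_cohort` from [generate_cohort()].
#' @param i subject index.
#' @param supersampling,margin forwarded to [render_phantom()].
#' @return as [make_longitudinal_pair()].
#' @export
simulate_subject <- function(cohort, i, supersampling = 4L, margin = 2) {
  s <- cohort$subjects[[i]]
  make_longitudinal_pair(s$spec, s$apposition, s$imaging, seed = s$seed,
                         supersampling = supersampling, margin = margin)
}
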