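#' Volume-of-interest configuration
#'
#' Geometry of the standard vertebral VOIs plus the tuning constants of the
#' automated ridge/threshold shell segmentation.
#'
#' @param subcortex_width width of the subcortical band inward of the
#'   endosteal surface, mm.
#' @param peel_width additional erosion before the peeled spongiosa, mm.
#' @param endplate_fraction fraction of the body height treated as endplate
#'   at each end (trimmed from the vertical cortex).
#' @param min_ridge_density global floor for the cortical density ridge,
#'   mgCaHA/cc; rays whose profile never reaches it fail.
#' @param boundary_fraction boundary placed where the radial profile falls
#'   below `background + boundary_fraction * (ridge - background)`
#'   (half-maximum convention by default).
#' @param n_angles number of radial rays per slice.
#' @param radial_step radial sampling step along each ray, mm.
#' @param smooth_sd SD (in angular bins) of the circular Gaussian used to
#'   regularize the recovered boundary radii.
#' @return object of class `voi_config`.
#' @export
voi_config <- function(subcortex_width = 2.0, peel_width = 2.0,
                       endplate_fraction = 0.15,
                       min_ridge_density = 200,
                       boundary_fraction = 0.5,
                       n_angles = 180L, radial_step = 0.1,
                       smooth_sd = 2) {
  stopifnot(subcortex_width >= 0, peel_width >= 0,
            endplate_fraction >= 0, endplate_fraction <= 0.5,
            boundary_fraction > 0, boundary_fraction < 1,
            n_angles >= 16L, radial_step > 0)
  structure(as.list(environment()), class = "voi_config")
}

#' VOI label codes
#'
#' Integer codes used in the `voi_labels` array of a segmentation:
#' EXCLUDED 0, VERTICAL_CORTEX 1, UPPER_ENDPLATE 2, LOWER_ENDPLATE 3,
#' SUBCORTEX 4, SPONGIOSA_PEELED 5.
#' @return named integer vector.
#' @export
voi_codes <- function() {
  c(EXCLUDED = 0L, VERTICAL_CORTEX = 1L, UPPER_ENDPLATE = 2L,
    LOWER_ENDPLATE = 3L, SUBCORTEX = 4L, SPONGIOSA_PEELED = 5L)
}

# Bilinear interpolation of a matrix at physical coordinates; NA outside.
interp_bilinear <- function(mat, px, py, sx, sy, ox, oy) {
  gx <- (px - ox) / sx + 1
  gy <- (py - oy) / sy + 1
  nx <- nrow(mat); ny <- ncol(mat)
  i0 <- floor(gx); j0 <- floor(gy)
  fx <- gx - i0; fy <- gy - j0
  ok <- i0 >= 1 & i0 <= nx - 1 & j0 >= 1 & j0 <= ny - 1
  out <- rep(NA_real_, length(gx))
  i0k <- i0[ok]; j0k <- j0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
  v00 <- mat[cbind(i0k, j0k)]
  v10 <- mat[cbind(i0k + 1, j0k)]
  v01 <- mat[cbind(i0k, j0k + 1)]
  v11 <- mat[cbind(i0k + 1, j0k + 1)]
  out[ok] <- v00 * (1 - fxk) * (1 - fyk) + v10 * fxk * (1 - fyk) +
    v01 * (1 - fxk) * fyk + v11 * fxk * fyk
  out
}

# Circular linear interpolation through NA gaps; NULL when all NA.
fill_circular <- function(v) {
  n <- length(v)
  if (!anyNA(v)) return(v)
  ok <- which(!is.na(v))
  if (length(ok) == 0) return(NULL)
  ext_x <- c(ok - n, ok, ok + n)
  ext_y <- rep(v[ok], 3)
  stats::approx(ext_x, ext_y, xout = seq_len(n))$y
}

# Circular Gaussian smoothing over angular bins.
smooth_circular <- function(v, sd_bins) {
  if (sd_bins <= 0) return(v)
  n <- length(v)
  hw <- max(1L, ceiling(3 * sd_bins))
  k <- dnorm((-hw):hw, sd = sd_bins)
  k <- k / sum(k)
  idx <- outer(seq_len(n), (-hw):hw, function(i, o) ((i + o - 1) %% n) + 1)
  as.numeric(matrix(v[idx], n) %*% k)
}

# Locate ridge and half-height boundary crossings along one radial profile.
# A short running mean tames voxel noise before the ridge and threshold
# crossings are read off (the ridge is >1 mm wide after blur, so a 0.3 mm
# window does not materially flatten it).
process_ray <- function(prof, r, cfg) {
  valid <- which(!is.na(prof))
  if (length(valid) < 10) return(NULL)
  prof <- prof[valid]; r <- r[valid]
  if (length(prof) >= 5)
    prof <- stats::filter(prof, rep(1 / 3, 3), sides = 2) |>
      (\(p) ifelse(is.na(p), prof, as.numeric(p)))()
  m <- which.max(prof)
  ridge <- prof[m]
  if (!is.finite(ridge) || ridge < cfg$min_ridge_density) return(NULL)
  n <- length(prof)
  n_tail <- max(5L, round(1 / cfg$radial_step))
  out_bg <- mean(prof[max(n - n_tail + 1, m + 1):n])
  inner <- prof[r < 0.55 * r[m]]
  if (length(inner) < 3) return(NULL)
  in_bg <- mean(inner)
  if (in_bg > 0.75 * ridge)
    return(list(cap = TRUE))
  thr_out <- out_bg + cfg$boundary_fraction * (ridge - out_bg)
  thr_in <- in_bg + cfg$boundary_fraction * (ridge - in_bg)

  cross <- function(i_from, i_to, thr) {
    step <- if (i_to >= i_from) 1L else -1L
    if (i_from == i_to) return(NA_real_)
    for (i in seq(i_from + step, i_to, by = step)) {
      if (prof[i] < thr) {
        j <- i - step
        fr <- (prof[j] - thr) / (prof[j] - prof[i])
        return(r[j] + fr * (r[i] - r[j]))
      }
    }
    NA_real_
  }
  r_p <- cross(m, n, thr_out)
  r_e <- cross(m, 1L, thr_in)
  if (is.na(r_p) || is.na(r_e)) return(NULL)
  list(cap = FALSE, r_peri = r_p, r_endo = r_e, ridge = ridge)
}

#' Segment the vertebral cortical shell
#'
#' Automated centroid-ray ridge detection: per axial slice, radial density
#' profiles from the body centroid locate the cortical density ridge; the
#' periosteal and endosteal boundaries are placed where the profile falls to
#' the half-height between ridge and the local background (soft tissue
#' outward, trabecular plateau inward), then regularized by circular
#' smoothing. VOIs (vertical cortex, endplates, 2 mm subcortex, peeled
#' spongiosa) are labeled per the configuration.
#'
#' @param volume calibrated [voxel_volume()] containing one vertebral body.
#' @param cfg a [voi_config()].
#' @return object of class `cortex_segmentation` with `cortical_mask`
#'   (logical array), `voi_labels` (integer array, see [voi_codes()]),
#'   `boundaries` (per-slice radii), `spacing`, `origin`.
#' @export
segment_cortex <- function(volume, cfg = voi_config()) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (!volume$calibrated) stop("segment_cortex needs a calibrated volume")
  d <- dim(volume$values)
  sp <- volume$spacing
  xs <- voxel_coords(volume, 1)
  ys <- voxel_coords(volume, 2)
  zs <- voxel_coords(volume, 3)
  theta <- seq(0, 2 * pi, length.out = cfg$n_angles + 1)[-(cfg$n_angles + 1)]
  ct <- cos(theta); st <- sin(theta)

  slices <- vector("list", d[3])
  slice_type <- rep("fail", d[3])
  for (k in seq_len(d[3])) {
    V <- volume$values[, , k]
    w <- pmax(V - 0.25 * cfg$min_ridge_density, 0)
    sw <- sum(w)
    if (sw <= 0) next
    cx <- sum(rowSums(w) * xs) / sw
    cy <- sum(colSums(w) * ys) / sw
    # sample out to the farthest grid corner; off-grid samples interpolate
    # to NA and are dropped per ray
    rmax <- sqrt(max(max(xs) - cx, cx - min(xs))^2 +
                 max(max(ys) - cy, cy - min(ys))^2)
    if (min(max(xs) - cx, cx - min(xs), max(ys) - cy, cy - min(ys)) < 1) next
    r <- seq(cfg$radial_step, rmax, by = cfg$radial_step)
    nr <- length(r)
    px <- cx + outer(r, ct)
    py <- cy + outer(r, st)
    vals <- matrix(interp_bilinear(V, as.numeric(px), as.numeric(py),
                                   sp[1], sp[2], xs[1], ys[1]),
                   nr, cfg$n_angles)
    rp <- re <- rep(NA_real_, cfg$n_angles)
    n_cap <- 0L
    for (j in seq_len(cfg$n_angles)) {
      res <- process_ray(vals[, j], r, cfg)
      if (is.null(res)) next
      if (isTRUE(res$cap)) { n_cap <- n_cap + 1L; next }
      rp[j] <- res$r_peri
      re[j] <- res$r_endo
    }
    n_ok <- sum(!is.na(rp))
    if (n_cap > cfg$n_angles / 2) { slice_type[k] <- "cap"; next }
    if (n_ok < 0.8 * cfg$n_angles) next
    rp <- smooth_circular(fill_circular(rp), cfg$smooth_sd)
    re <- smooth_circular(fill_circular(re), cfg$smooth_sd)
    if (any(re >= rp)) next
    slice_type[k] <- "wall"
    slices[[k]] <- list(k = k, z = zs[k], centroid = c(cx, cy),
                        theta = theta, r_peri = rp, r_endo = re,
                        r_mid = (rp + re) / 2)
  }

  wall_ks <- which(slice_type == "wall")
  if (length(wall_ks) == 0)
    stop("segmentation failure: no cortical ridge above ",
         cfg$min_ridge_density, " mg/cc on any slice")

  body_ks <- which(slice_type %in% c("wall", "cap"))
  z_lo <- zs[min(body_ks)] - sp[3] / 2
  z_hi <- zs[max(body_ks)] + sp[3] / 2
  # the vertical band is anchored to the wall-slice extent: blur smears the
  # endplates over neighbouring slices, so the combined wall+cap extent
  # overstates the body height and would under-trim
  w_lo <- zs[min(wall_ks)] - sp[3] / 2
  w_hi <- zs[max(wall_ks)] + sp[3] / 2
  Hw <- w_hi - w_lo
  band_lo <- w_lo + cfg$endplate_fraction * Hw
  band_hi <- w_hi - cfg$endplate_fraction * Hw
  z_mid <- (z_lo + z_hi) / 2

  codes <- voi_codes()
  cortical_mask <- array(FALSE, dim = d)
  voi <- array(codes[["EXCLUDED"]], dim = d)
  gx <- matrix(xs, d[1], d[2])
  gy <- matrix(ys, d[1], d[2], byrow = TRUE)

  for (k in wall_ks) {
    b <- slices[[k]]
    dx <- gx - b$centroid[1]
    dy <- gy - b$centroid[2]
    rho <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx) %% (2 * pi)
    rp_v <- interp_circular(b$theta, b$r_peri, th)
    re_v <- interp_circular(b$theta, b$r_endo, th)
    in_cortex <- rho >= re_v & rho < rp_v
    cortical_mask[, , k] <- in_cortex

    in_band <- b$z >= band_lo & b$z <= band_hi
    lab <- matrix(codes[["EXCLUDED"]], d[1], d[2])
    if (in_band) {
      # interior zones from the signed distance to the endosteal surface
      ex <- b$centroid[1] + b$r_endo * cos(b$theta)
      ey <- b$centroid[2] + b$r_endo * sin(b$theta)
      de <- matrix(cc_polygon_signed_distance(ex, ey,
                                              as.numeric(gx), as.numeric(gy)),
                   d[1], d[2])
      inside <- de < 0 & !in_cortex
      lab[inside & de >= -cfg$subcortex_width] <- codes[["SUBCORTEX"]]
      lab[inside & de < -(cfg$subcortex_width + cfg$peel_width)] <-
        codes[["SPONGIOSA_PEELED"]]
      lab[in_cortex] <- codes[["VERTICAL_CORTEX"]]
    } else {
      lab[in_cortex] <- if (b$z > z_mid) codes[["UPPER_ENDPLATE"]] else
        codes[["LOWER_ENDPLATE"]]
    }
    voi[, , k] <- lab
  }

  structure(
    list(cortical_mask = cortical_mask, voi_labels = voi,
         boundaries = slices[wall_ks], slice_type = slice_type,
         spacing = sp, origin = volume$origin,
         body_z_range = c(z_lo, z_hi), band_z_range = c(band_lo, band_hi),
         cfg = cfg),
    class = "cortex_segmentation"
  )
}

# Interpolate per-angle radii at arbitrary angles (uniform circular grid).
interp_circular <- function(theta_grid, radii, th) {
  n <- length(theta_grid)
  dth <- theta_grid[2] - theta_grid[1]
  pos <- (th - theta_grid[1]) / dth
  i0 <- floor(pos)
  fr <- pos - i0
  i0 <- (as.integer(i0) %% n) + 1L
  i1 <- (i0 %% n) + 1L
  radii[i0] * (1 - fr) + radii[i1] * fr
}

#' @export
print.cortex_segmentation <- function(x, ...) {
  cat(sprintf(
    "<cortex_segmentation> %d wall slices, %d cortical voxels, %d vertical\n",
    length(x$boundaries), sum(x$cortical_mask),
    sum(x$voi_labels == voi_codes()[["VERTICAL_CORTEX"]])))
  invisible(x)
}

#' Vertical-cortex voxel mask
#'
#' The cortical mask restricted to the vertical wall (endplate bands trimmed
#' at each end per the segmentation's `endplate_fraction`).
#'
#' @param seg a [segment_cortex()] result.
#' @return logical array.
#' @export
vertical_cortex_only <- function(seg) {
  stopifnot(inherits(seg, "cortex_segmentation"))
  m <- seg$voi_labels == voi_codes()[["VERTICAL_CORTEX"]]
  if (!any(m)) stop("vertical cortex is empty (endplate_fraction too large?)")
  array(m, dim = dim(seg$voi_labels))
}
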