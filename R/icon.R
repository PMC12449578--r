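#' Cortex forward-model parameters
#'
#' Parameters of the Gaussian-convolved piecewise-constant model of the
#' radial BMD profile: a trabecular plateau (edge spread function) inside,
#' a compact-bone band of fixed reference mineralization (line spread
#' function) and soft tissue outside.
#'
#' @param center cortical mid-line (ridge) position, mm.
#' @param width deconvolved cortical width, mm.
#' @param sigma effective Gaussian PSF sigma along the profile, mm.
#' @param plateau spongiosa plateau density, mgCaHA/cc.
#' @param soft_tissue soft-tissue density, mgCaHA/cc.
#' @param tmd_ref fixed compact-bone mineralization, mgCaHA/cc.
#' @param rms residual RMS of the fit (weighted), mgCaHA/cc.
#' @param converged logical convergence flag.
#' @param degenerate logical; `TRUE` when the width collapsed to its bound.
#' @return object of class `cortex_model`.
#' @export
cortex_model <- function(center, width, sigma, plateau, soft_tissue,
                         tmd_ref = 1100, rms = NA_real_, converged = NA,
                         degenerate = FALSE) {
  stopifnot(width >= 0, sigma > 0, plateau >= 0, is.finite(center))
  structure(
    list(center = center, width = width, sigma = sigma, plateau = plateau,
         soft_tissue = soft_tissue, tmd_ref = tmd_ref, rms = rms,
         converged = converged, degenerate = degenerate),
    class = "cortex_model"
  )
}

#' @export
print.cortex_model <- function(x, ...) {
  cat(sprintf(
    paste0("<cortex_model> width %.1f um, centre %.3f mm, sigma %.3f mm,\n",
           "  plateau %.1f, soft tissue %.1f mgCaHA/cc (rms %.2f%s%s)\n"),
    x$width * 1000, x$center, x$sigma, x$plateau, x$soft_tissue, x$rms,
    if (isTRUE(x$converged)) ", converged" else "",
    if (isTRUE(x$degenerate)) ", DEGENERATE" else ""))
  invisible(x)
}

#' Apposition model
#'
#' Widths of new-matrix slabs attached flush to the baseline cortical band,
#' imaged at `mineralization_fraction * tmd_ref` density.
#'
#' @param a_e endosteal slab width, mm.
#' @param a_p periosteal slab width, mm.
#' @param mineralization_fraction fraction in (0, 1].
#' @param plateau,soft_tissue follow-up background levels, mgCaHA/cc.
#' @param baseline the baseline [cortex_model()].
#' @param rms,converged,at_bound fit diagnostics.
#' @return object of class `apposition_model`; `delta_w = a_e + a_p`.
#' @export
apposition_model <- function(a_e, a_p, mineralization_fraction = 0.5,
                             plateau = NA_real_, soft_tissue = NA_real_,
                             baseline = NULL, rms = NA_real_,
                             converged = NA, at_bound = FALSE) {
  stopifnot(a_e >= 0, a_p >= 0,
            mineralization_fraction > 0, mineralization_fraction <= 1)
  structure(
    list(a_e = a_e, a_p = a_p, delta_w = a_e + a_p,
         mineralization_fraction = mineralization_fraction,
         plateau = plateau, soft_tissue = soft_tissue,
         baseline = baseline, rms = rms, converged = converged,
         at_bound = at_bound),
    class = "apposition_model"
  )
}

# Gaussian-convolved indicator of the band [l, u].
band_response <- function(x, l, u, sigma) {
  pnorm((u - x) / sigma) - pnorm((l - x) / sigma)
}

#' Evaluate the ESF + LSF forward model
#'
#' Closed-form prediction of the blurred radial BMD profile. With the
#' distance axis x positive in the periosteal direction, the un-blurred
#' profile is plateau P for x below the endosteal edge `e = center - width/2`,
#' `tmd_ref` over the cortical band, and soft tissue S beyond the periosteal
#' edge `p = center + width/2`; Gaussian blur turns each region indicator
#' into a difference of normal CDFs. Apposition slabs of density
#' `f * tmd_ref` attach flush to the band: endosteal `[e - a_e, e]`,
#' periosteal `[p, p + a_p]`.
#'
#' @param model a [cortex_model()].
#' @param distances signed distances at which to predict, mm.
#' @param apposition optional [apposition_model()].
#' @return predicted BMD, mgCaHA/cc.
#' @export
forward_model <- function(model, distances, apposition = NULL) {
  stopifnot(inherits(model, "cortex_model"), model$sigma > 0)
  x <- as.numeric(distances)
  e <- model$center - model$width / 2
  p <- model$center + model$width / 2
  S <- model$soft_tissue
  P <- model$plateau
  pred <- S + (P - S) * pnorm((e - x) / model$sigma) +
    (model$tmd_ref - S) * band_response(x, e, p, model$sigma)
  if (!is.null(apposition)) {
    stopifnot(inherits(apposition, "apposition_model"))
    rho <- apposition$mineralization_fraction * model$tmd_ref
    pred <- pred +
      rho * band_response(x, e - apposition$a_e, e, model$sigma) +
      rho * band_response(x, p, p + apposition$a_p, model$sigma)
  }
  pred
}

#' Spongiosa background of a fitted model
#'
#' The soft-tissue + plateau edge-spread background
#' `S + (P - S) * Phi((e - x) / sigma)` without the cortical band.
#' @param model a [cortex_model()].
#' @param distances signed distances, mm.
#' @return background BMD, mgCaHA/cc.
#' @export
esf_background <- function(model, distances) {
  x <- as.numeric(distances)
  e <- model$center - model$width / 2
  model$soft_tissue +
    (model$plateau - model$soft_tissue) * pnorm((e - x) / model$sigma)
}

profile_xyw <- function(profile) {
  stopifnot(inherits(profile, "radial_profile"))
  keep <- profile$count > 0 & is.finite(profile$mean_bmd)
  if (sum(keep) < 8) stop("profile has too few populated bins to fit")
  list(x = profile$bin_center[keep], y = profile$mean_bmd[keep],
       w = profile$count[keep])
}

#' Fit the baseline cortex model to a radial profile
#'
#' Weighted nonlinear least squares (bounded Levenberg-Marquardt) over
#' centre, width, plateau, soft tissue and sigma; the compact-bone
#' mineralization is held fixed at `tmd_ref`. Sigma is initialized at the
#' scanner-specific PSF value and box-bounded to +/-50% of it. A
#' deterministic multistart over three centre offsets (-1, 0, +1 layers)
#' keeps the fit off secondary minima.
#'
#' @param profile a [extract_profile()] result spanning the full cortex.
#' @param init_width initial cortical width, mm (typically wCt.Th / 1000).
#' @param scanner_sigma scanner PSF sigma, mm.
#' @param tmd_ref fixed mineralization, mgCaHA/cc.
#' @return a converged [cortex_model()] with diagnostics.
#' @export
fit_baseline <- function(profile, init_width, scanner_sigma,
                         tmd_ref = 1100) {
  stopifnot(init_width > 0, scanner_sigma > 0)
  d <- profile_xyw(profile)
  h <- attr(profile, "layer_thickness")
  if (is.null(h)) h <- 0.2
  sw <- sqrt(d$w)

  ridge0 <- d$x[which.max(d$y)]
  P0 <- mean(d$y[d$x < ridge0 - 2])
  if (!is.finite(P0)) P0 <- min(d$y)
  S0 <- mean(d$y[d$x > ridge0 + 2])
  if (!is.finite(S0)) S0 <- 0
  P0 <- min(max(P0, 0), 590)
  S0 <- min(max(S0, -90), 290)

  # a usable profile must carry an interior density ridge clearly above both
  # background levels; a monotone or flat profile has no cortical band
  m_idx <- which.max(d$y)
  band_amp <- d$y[m_idx] - max(P0, S0)
  if (m_idx <= 3 || m_idx > length(d$y) - 3 || band_amp < 50) {
    return(cortex_model(center = ridge0, width = 0, sigma = scanner_sigma,
                        plateau = P0, soft_tissue = S0, tmd_ref = tmd_ref,
                        rms = NA_real_, converged = FALSE,
                        degenerate = TRUE))
  }

  lower <- c(center = ridge0 - 1.5, width = 1e-4,
             sigma = 0.5 * scanner_sigma, plateau = 0, soft_tissue = -100)
  upper <- c(center = ridge0 + 1.5, width = 3,
             sigma = 1.5 * scanner_sigma, plateau = 600, soft_tissue = 300)

  resid_fun <- function(par) {
    m <- cortex_model(par[1], par[2], par[3], par[4], par[5],
                      tmd_ref = tmd_ref)
    sw * (d$y - forward_model(m, d$x))
  }

  best <- NULL
  for (off in c(-h, 0, h)) {
    start <- c(center = min(max(ridge0 + off, lower[1]), upper[1]),
               width = min(max(init_width, 2 * lower[2]), upper[2]),
               sigma = scanner_sigma, plateau = P0, soft_tissue = S0)
    fit <- try(minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("baseline fit failed to converge (multistart exhausted)")
  ok <- best$info %in% 1:4
  if (!ok)
    stop("baseline fit did not converge: ", best$message)
  par <- best$par
  degen <- par[2] <= lower[2] * 1.05 + 1e-9 || par[2] < h / 20
  cortex_model(center = unname(par[1]), width = unname(par[2]),
               sigma = unname(par[3]), plateau = unname(par[4]),
               soft_tissue = unname(par[5]), tmd_ref = tmd_ref,
               rms = sqrt(best$deviance / sum(d$w)),
               converged = ok, degenerate = degen)
}

#' Subtract the fitted spongiosa background from a profile
#'
#' Removes `S + (P - S) * Phi((e - x)/sigma)` evaluated at the bin centres,
#' leaving the cortical band signal centred on zero in the spongiosa tail.
#' The removed background is stored in the `"esf_background"` attribute so
#' the operation is exactly invertible.
#'
#' @param profile a [extract_profile()] result.
#' @param model the fitted [cortex_model()].
#' @return a `radial_profile` of residuals.
#' @export
subtract_spongiosa <- function(profile, model) {
  stopifnot(inherits(profile, "radial_profile"),
            inherits(model, "cortex_model"))
  bg <- esf_background(model, profile$bin_center)
  out <- profile
  out$mean_bmd <- profile$mean_bmd - bg
  out$bmc_per_area <- out$mean_bmd * attr(profile, "layer_thickness") / 10
  attr(out, "esf_background") <- bg
  out
}

#' Fit apposition slabs to a follow-up profile
#'
#' Holds the baseline geometry (centre, width, sigma) fixed and fits the
#' endosteal and periosteal slab widths plus follow-up plateau and
#' soft-tissue levels by the same weighted least squares. Slab widths are
#' bounded below at zero; resorption is absorbed by the background levels.
#'
#' @param baseline a converged [fit_baseline()] model.
#' @param followup_profile [extract_profile()] of the follow-up scan on the
#'   baseline segmentation.
#' @param f assumed mineralization fraction of new matrix, in (0, 1].
#' @return an [apposition_model()]; `delta_w` (mm) is the estimated total
#'   cortical thickness change.
#' @export
fit_apposition <- function(baseline, followup_profile, f = 0.5) {
  stopifnot(inherits(baseline, "cortex_model"))
  if (isTRUE(baseline$degenerate)) stop("baseline model is degenerate")
  if (f <= 0 || f > 1) stop("mineralization fraction must be in (0, 1]")
  d <- profile_xyw(followup_profile)
  sw <- sqrt(d$w)

  lower <- c(a_e = 0, a_p = 0, plateau = 0, soft_tissue = -100)
  upper <- c(a_e = 3, a_p = 3, plateau = 600, soft_tissue = 300)
  start <- c(a_e = 0.02, a_p = 0.02,
             plateau = min(max(baseline$plateau, 0), 600),
             soft_tissue = min(max(baseline$soft_tissue, -100), 300))

  resid_fun <- function(par) {
    m <- cortex_model(baseline$center, baseline$width, baseline$sigma,
                      par[3], par[4], tmd_ref = baseline$tmd_ref)
    a <- apposition_model(par[1], par[2], f)
    sw * (d$y - forward_model(m, d$x, apposition = a))
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$info %in% 1:4)
    stop("apposition fit did not converge: ", fit$message)
  par <- fit$par
  at_bound <- par[1] >= upper[1] - 1e-6 || par[2] >= upper[2] - 1e-6
  apposition_model(a_e = unname(par[1]), a_p = unname(par[2]),
                   mineralization_fraction = f,
                   plateau = unname(par[3]), soft_tissue = unname(par[4]),
                   baseline = baseline,
                   rms = sqrt(fit$deviance / sum(d$w)),
                   converged = TRUE, at_bound = at_bound)
}

#' Deconvolved cortical thickness
#'
#' The width parameter of a fitted cortex model, in micrometres. For
#' longitudinal analysis the follow-up thickness is the baseline width plus
#' the fitted apposition `delta_w`.
#'
#' @param model a converged [cortex_model()].
#' @return thickness in micrometres.
#' @export
dcctth <- function(model) {
  stopifnot(inherits(model, "cortex_model"))
  if (isTRUE(model$degenerate))
    stop("model is degenerate: no cortical band was identified")
  model$width * 1000
}

#' Serialize a fit result to JSON
#' @param model a `cortex_model` or `apposition_model`.
#' @param path JSON file.
#' @return `path`, invisibly.
#' @export
write_fit <- function(model, path) {
  m <- unclass(model)
  if (!is.null(m$baseline)) m$baseline <- unclass(m$baseline)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
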