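#' Viscous-fluid stage configuration
#'
#' @param sigma_fluid_mm width (mm) of the Gaussian kernel that converts the
#'   force field into a velocity field (the convolution replacing the
#'   successive-over-relaxation Navier-Stokes solve).
#' @param sigma_field_mm width (mm) of the Gaussian applied to the
#'   displacement field after each increment to keep it continuous.
#' @param max_step_mm per-iteration displacement cap; the effective time
#'   step is `max_step_mm / max |v|`.  `NULL` = `0.4 * min(voxel spacing)`.
#' @param jac_min regridding threshold on the minimum Jacobian determinant,
#'   in (0, 1).
#' @param max_iter iteration cap per level.
#' @param transport include the material transport term `-J_u v` in the
#'   increment (`TRUE`, default) or use the simple update `u + dt v`.
#' @param bins,parzen_sigma_bins MI objective settings (`NULL` bins =
#'   adaptive).
#' @param patience consecutive rejected/worsening iterations tolerated
#'   before returning the best field so far.
#' @param plateau_tol,plateau_window MI plateau stopping rule.
#' @param regrid enable the regridding safeguard.
#' @param accept_k minimum-improvement scale, as in [ffd_config()].
#' @param normalize `"max"` (default): raw force with
#'   `dt = max_step_mm / max |v|` -- the per-voxel force magnitude acts as
#'   an evidence weight, which is robust when the similarity landscape is
#'   noisy; `"demons"`: the force is divided per voxel by
#'   `|grad m|^2 + delta` before the convolution, so well- and
#'   weakly-contrasted regions advance at comparable speeds (time step from
#'   the 95th-percentile speed, per-voxel cap at twice the nominal step) --
#'   faster on clean mono-modal pairs, unstable on noisy ones.
#' @export
fluid_config <- function(sigma_fluid_mm = 4.0, sigma_field_mm = 2.0,
                         max_step_mm = NULL, jac_min = 0.5, max_iter = 30,
                         transport = TRUE, bins = NULL, parzen_sigma_bins = 1,
                         patience = 5, plateau_tol = 1e-4, plateau_window = 5,
                         regrid = TRUE, normalize = c("max", "demons"),
                         accept_k = 0.05) {
  stopifnot(sigma_fluid_mm > 0, sigma_field_mm >= 0,
            jac_min > 0, jac_min < 1, max_iter >= 0)
  list(sigma_fluid_mm = sigma_fluid_mm, sigma_field_mm = sigma_field_mm,
       max_step_mm = max_step_mm, jac_min = jac_min, max_iter = max_iter,
       transport = transport, bins = bins,
       parzen_sigma_bins = parzen_sigma_bins, patience = patience,
       plateau_tol = plateau_tol, plateau_window = plateau_window,
       regrid = regrid, normalize = match.arg(normalize),
       accept_k = accept_k)
}

# componentwise Gaussian smoothing of a vector field, sigma in mm
smooth_vectors <- function(vectors, spacing, sigma_mm) {
  d <- dim(vectors)[1:3]
  sig_vox <- sigma_mm / spacing
  out <- array(0, dim = dim(vectors))
  for (c in 1:3)
    out[, , , c] <- array(cpp_gauss3(as.numeric(vectors[, , , c]), d, sig_vox),
                          dim = d)
  out
}

#' Convolve a force field into a fluid velocity field
#'
#' The fluid velocity is not obtained from a successive-over-relaxation
#' solve of the Navier-Stokes equations but simplified to a componentwise
#' convolution of the force field with a unit-sum Gaussian kernel of width
#' `sigma_fluid_mm` (in physical units).
#'
#' @param force a `forcefield` (from [mi_force()]) or displacement-field-
#'   shaped object.
#' @param sigma_fluid_mm kernel width in mm (> 0).
#' @param spacing voxel spacing in mm (defaults to the force's).
#' @return An object of the same shape/class holding the velocity.
#' @export
velocity_from_force <- function(force, sigma_fluid_mm, spacing = force$spacing) {
  stopifnot(sigma_fluid_mm > 0)
  out <- force
  out$vectors <- smooth_vectors(force$vectors, spacing, sigma_fluid_mm)
  out
}

#' One fluid displacement increment
#'
#' `u_new = u + dt (v - J_u v)` where `J_u` is the central-difference
#' Jacobian of `u` in physical units (the material transport term), or
#' `u + dt v` when `transport = FALSE`.
#'
#' @param u current [displacement_field()].
#' @param v velocity field on the same grid.
#' @param dt_effective dimensionless step scale.
#' @param transport include the transport term.
#' @return The updated [displacement_field()].
#' @export
fluid_increment <- function(u, v, dt_effective, transport = TRUE) {
  if (!same_grid(u, v)) stop_grid_mismatch("fluid_increment", u, v)
  w <- transport_velocity(u, v$vectors, transport)
  out <- u$vectors + dt_effective * w
  if (any(!is.finite(out))) stop("fluid_increment: non-finite result")
  displacement_field(out, u$spacing, u$origin)
}

# v - J_u v (or v), returned as a plain (nx,ny,nz,3) array
transport_velocity <- function(u, vvec, transport = TRUE) {
  if (!transport) return(vvec)
  w <- vvec
  for (ci in 1:3) {
    adv <- 0
    for (ax in 1:3)
      adv <- adv + diff_axis(u$vectors[, , , ci], ax, u$spacing[ax]) *
        vvec[, , , ax]
    w[, , , ci] <- vvec[, , , ci] - adv
  }
  w
}

#' Gaussian smoothing of a displacement field
#'
#' Componentwise, in physical units; `sigma_field_mm = 0` is the identity
#' and constant fields are fixed points (unit-sum kernel with boundary
#' renormalization).
#'
#' @param u a [displacement_field()].
#' @param sigma_field_mm kernel width in mm (>= 0).
#' @return The smoothed [displacement_field()].
#' @export
smooth_field <- function(u, sigma_field_mm) {
  stopifnot(sigma_field_mm >= 0)
  if (sigma_field_mm == 0) return(u)
  displacement_field(smooth_vectors(u$vectors, u$spacing, sigma_field_mm),
                     u$spacing, u$origin)
}

#' Regridding safeguard for the fluid flow
#'
#' When the accumulated residual deformation approaches folding
#' (`min det(I + grad u) < jac_min`), the currently warped moving image
#' becomes the new template and the residual field is reset to zero; the
#' caller composes the stored fields so the total warp is preserved.
#'
#' @param u residual [displacement_field()] since the last regrid.
#' @param template current template [image3d()] (the image `u` deforms).
#' @param jac_min threshold in (0, 1).
#' @return A list `(new_template, residual_u, regridded)`; unchanged inputs
#'   with `regridded = FALSE` when the Jacobian is healthy.
#' @export
regrid_if_needed <- function(u, template, jac_min) {
  mj <- min(jacobian_determinant(u)$voxels)
  if (mj < jac_min) {
    list(new_template = apply_warp(template, u, "linear"),
         residual_u = zero_field(template), regridded = TRUE)
  } else {
    list(new_template = template, residual_u = u, regridded = FALSE)
  }
}

#' Viscous-fluid refinement stage
#'
#' Iterates force -> Gaussian velocity -> displacement increment ->
#' field smoothing -> re-warp -> MI evaluation, keeping a trial update only
#' when it improves both MI estimators (hard-binned and PV-binned, each
#' Parzen-smoothed) by more than the statistical resolution of the
#' histogram; rejected trials halve an adaptive step scale.  Stops at
#' `max_iter`, when the step scale collapses, when MI plateaus, or after
#' `patience` consecutive rejections (the divergence guard).  Returns the
#' best-MI total field encountered -- including the initial one, so a pair
#' that is already registered comes back unchanged.
#'
#' @param fixed reference [image3d()].
#' @param moving [image3d()] to be deformed (unwarped; `u_init` carries any
#'   previous alignment).
#' @param u_init initial [displacement_field()] on `fixed`'s grid.
#' @param cfg a [fluid_config()].
#' @return A list with `field` (total [displacement_field()]), `warped`
#'   ([image3d()]), and `trace` (data.frame: iteration, mi, step_mm,
#'   min_jacobian, regridded, accepted).
#' @export
fluid_stage <- function(fixed, moving, u_init = zero_field(fixed),
                        cfg = fluid_config()) {
  if (!same_grid(fixed, u_init)) stop_grid_mismatch("fluid_stage", fixed, u_init)
  bins <- if (is.null(cfg$bins)) adaptive_bins(length(fixed$voxels)) else cfg$bins
  max_step <- if (is.null(cfg$max_step_mm)) 0.4 * min(fixed$spacing) else cfg$max_step_mm
  rf <- intensity_window(fixed)
  rm_ <- intensity_window(moving)
  fvec <- as.vector(fixed$voxels)
  bg <- min(moving$voxels)
  mi_of <- function(w) smoothed_mi(fvec, as.vector(w$voxels), bins, rf, rm_,
                                   cfg$parzen_sigma_bins)
  pv_of <- function(w) smoothed_mi_pv(fvec, as.vector(w$voxels), bins, rf, rm_,
                                      cfg$parzen_sigma_bins)
  u_base <- NULL           # composed field absorbed at regrids
  template <- moving
  u_res <- u_init
  total_field <- function(res) if (is.null(u_base)) res else compose_fields(u_base, res)
  warped <- apply_warp(template, u_res, "linear", background = bg)
  mi_cur <- mi_of(warped)
  pv_cur <- pv_of(warped)
  tau <- max(1e-7, cfg$accept_k * bins^2 / length(fixed$voxels))
  best <- list(field = u_init, warped = warped, mi = mi_cur)
  trace <- data.frame(iteration = 0L, mi = mi_cur, step_mm = 0,
                      min_jacobian = min(jacobian_determinant(u_res)$voxels),
                      regridded = FALSE, accepted = TRUE)
  scale <- 1
  bad <- 0L
  accepted_mi <- mi_cur
  for (it in seq_len(cfg$max_iter)) {
    Fv <- mi_force(fixed, warped, bins = bins,
                   parzen_sigma_bins = cfg$parzen_sigma_bins,
                   range_fixed = rf, range_moving = rm_)
    if (cfg$normalize == "demons") {
      gw <- image_gradient(warped)
      g2 <- gw[, , , 1]^2 + gw[, , , 2]^2 + gw[, , , 3]^2
      delta <- 0.01 * mean(g2)
      if (delta > 0)
        for (c in 1:3) Fv$vectors[, , , c] <- Fv$vectors[, , , c] / (g2 + delta)
    }
    v <- velocity_from_force(Fv, cfg$sigma_fluid_mm)
    w <- transport_velocity(u_res, v$vectors, cfg$transport)
    vmax <- max(abs(w))
    if (!is.finite(vmax) || vmax == 0) break
    if (cfg$normalize == "demons") {
      mag <- sqrt(w[, , , 1]^2 + w[, , , 2]^2 + w[, , , 3]^2)
      dt <- scale * max_step / max(quantile(mag, 0.95), 1e-12)
      # cap outlier voxels at twice the nominal step
      cap <- pmin(1, (2 * max_step) / pmax(mag * dt, 1e-12))
      w <- w * array(rep(cap, 3), dim = dim(w))
    } else {
      dt <- scale * max_step / vmax
    }
    u_try <- smooth_field(displacement_field(u_res$vectors + dt * w,
                                             u_res$spacing, u_res$origin),
                          cfg$sigma_field_mm)
    w_try <- apply_warp(template, u_try, "linear", background = bg)
    mi_try <- mi_of(w_try)
    pv_try <- pv_of(w_try)
    accepted <- mi_try > mi_cur + tau && pv_try > pv_cur + tau
    step_mm <- dt * vmax
    regridded <- FALSE
    if (accepted) {
      u_res <- u_try
      warped <- w_try
      mi_cur <- mi_try
      pv_cur <- pv_try
      bad <- 0L
      scale <- min(1, scale * 2)  # recover step size after backtracking
      if (mi_cur > best$mi) {
        best <- list(field = total_field(u_res), warped = warped, mi = mi_cur)
      }
      if (cfg$regrid) {
        rg <- regrid_if_needed(u_res, template, cfg$jac_min)
        if (rg$regridded) {
          u_base <- total_field(u_res)
          template <- apply_warp(moving, u_base, "linear", background = bg)
          u_res <- zero_field(fixed)
          warped <- template
          pv_cur <- pv_of(warped)
          regridded <- TRUE
        }
      }
    } else {
      scale <- scale / 2
      bad <- bad + 1L
    }
    trace <- rbind(trace, data.frame(
      iteration = it, mi = mi_cur, step_mm = step_mm,
      min_jacobian = min(jacobian_determinant(u_res)$voxels),
      regridded = regridded, accepted = accepted))
    if (bad >= cfg$patience || scale < 2^-6) break
    acc <- trace$mi[trace$accepted]
    wdw <- cfg$plateau_window
    if (length(acc) > wdw) {
      prev <- acc[length(acc) - wdw]
      if ((mi_cur - prev) < cfg$plateau_tol * max(abs(prev), 1e-8)) break
    }
  }
  list(field = best$field, warped = best$warped, trace = trace)
}
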