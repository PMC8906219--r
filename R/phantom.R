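#' Specification of the digital head-and-neck phantom
#'
#' The phantom stands in for a planning-CT volume: a soft-tissue body
#' ellipsoid containing a bright "vertebral column" of stacked
#' high-intensity blocks with a spinal canal, an airway, an air-filled
#' oral cavity, a bony mandible, a parotid-like gland, and five small
#' marker discs (P1..P5) on the column.  Defaults are 64^3 voxels at
#' isotropic 2 mm for test speed; the clinical pCT geometry
#' (1.27 x 1.27 x 3 mm) is available via `spacing`.
#'
#' @param shape length-3 integer, voxels per axis (>= 16).
#' @param spacing length-3 mm voxel size.
#' @param seed RNG seed; every generated artifact is a pure function of
#'   (spec, seed).
#' @param intensities named list of tissue levels (background, air, soft,
#'   bone); must satisfy bone > soft > air >= background.
#' @param texture_sd amplitude of the smooth soft-tissue texture field.
#' @param noise_sd additive noise on the clean phantom (kept small; the
#'   CBCT-style degradation adds its own).
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(2, 2, 2),
                         seed = 1,
                         intensities = list(background = -1000, air = -850,
                                            soft = 40, bone = 700),
                         texture_sd = 30, noise_sd = 5) {
  shape <- as.integer(rep_len(shape, 3L))
  if (any(shape < 16L)) stop("phantom_spec: shape must be >= 16 per axis")
  ii <- intensities
  if (!(ii$bone > ii$soft && ii$soft > ii$air && ii$air >= ii$background))
    stop("phantom_spec: need bone > soft > air >= background")
  list(shape = shape, spacing = rep_len(as.numeric(spacing), 3L),
       seed = as.integer(seed), intensities = ii,
       texture_sd = texture_sd, noise_sd = noise_sd)
}

# normalized coordinate arrays in [0,1] for a shape
unit_coords <- function(shape) {
  list(x = array(rep((seq_len(shape[1]) - 1) / (shape[1] - 1),
                     times = shape[2] * shape[3]), dim = shape),
       y = array(rep(rep((seq_len(shape[2]) - 1) / (shape[2] - 1),
                         each = shape[1]), times = shape[3]), dim = shape),
       z = array(rep((seq_len(shape[3]) - 1) / (shape[3] - 1),
                     each = shape[1] * shape[2]), dim = shape))
}

ellipsoid <- function(co, centre, semi) {
  ((co$x - centre[1]) / semi[1])^2 + ((co$y - centre[2]) / semi[2])^2 +
    ((co$z - centre[3]) / semi[3])^2 <= 1
}

#' Generate the digital phantom
#'
#' @param spec a [phantom_spec()].
#' @return A list with `image` ([image3d()]), `masks` (named list of
#'   pairwise-disjoint [binary_mask()]s: larynx, spinal_cord, oral_cavity,
#'   mandible, parotid, P1..P5), `landmarks` ([landmark_set()] of marker
#'   centroids), and `body` (the body [binary_mask()], overlapping the
#'   organs by construction and therefore kept out of `masks`).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  with_seed(spec$seed, {
    sh <- spec$shape; ii <- spec$intensities
    co <- unit_coords(sh)
    vol <- array(ii$background, dim = sh)
    body <- ellipsoid(co, c(0.5, 0.5, 0.5), c(0.44, 0.42, 0.49))
    vol[body] <- ii$soft
    # vertebral column: stacked bone blocks with disc gaps, posterior
    col_xy <- (abs(co$x - 0.5) < 0.09) & (abs(co$y - 0.68) < 0.09)
    zn <- co$z
    block <- (floor(zn * 12) %% 3) != 2      # 2-of-3 duty cycle along z
    column <- col_xy & block & body & (zn > 0.08) & (zn < 0.92)
    # spinal canal + cord inside the column footprint
    canal <- (abs(co$x - 0.5) < 0.03) & (abs(co$y - 0.68) < 0.03) & body &
      (zn > 0.05) & (zn < 0.95)
    vol[column & !canal] <- ii$bone
    cord <- canal & (zn > 0.1) & (zn < 0.9)
    vol[cord] <- ii$soft - 15
    # airway: anterior tube; larynx = its mid section plus a soft collar
    airway <- ((co$x - 0.5)^2 + (co$y - 0.34)^2 < 0.045^2) & body &
      (zn > 0.15) & (zn < 0.85)
    vol[airway] <- ii$air
    larynx <- ((co$x - 0.5)^2 + (co$y - 0.34)^2 < 0.075^2) & body &
      (zn > 0.40) & (zn < 0.58)
    # oral cavity: air pocket near the top
    oral <- ellipsoid(co, c(0.5, 0.40, 0.82), c(0.10, 0.09, 0.07)) & body
    vol[oral] <- ii$air
    # mandible: bone bar anterior-superior
    mandible <- ellipsoid(co, c(0.5, 0.25, 0.74), c(0.16, 0.05, 0.05)) & body
    vol[mandible] <- ii$bone - 80
    # parotid: lateral soft gland
    parotid <- ellipsoid(co, c(0.76, 0.45, 0.70), c(0.08, 0.10, 0.09)) & body
    vol[parotid] <- ii$soft + 45
    # markers: small discs (radius 2 voxels, 1 slice) on the column surface
    marker_z <- c(0.80, 0.72, 0.52, 0.44, 0.18)
    marker_masks <- list()
    for (p in seq_along(marker_z)) {
      kz <- 1 + round(marker_z[p] * (sh[3] - 1))
      side <- if (p %% 2 == 1) -1 else 1
      cx <- 1 + round((0.5 + side * 0.11) * (sh[1] - 1))
      cy <- 1 + round(0.68 * (sh[2] - 1))
      mk <- array(FALSE, dim = sh)
      for (di in -2:2) for (dj in -2:2) {
        if (di^2 + dj^2 <= 4 &&
            cx + di >= 1 && cx + di <= sh[1] && cy + dj >= 1 && cy + dj <= sh[2])
          mk[cx + di, cy + dj, kz] <- TRUE
      }
      vol[mk] <- ii$bone + 150
      marker_masks[[paste0("P", p)]] <- mk
    }
    # smooth soft-tissue texture so similarity metrics have structure
    tex <- array(rnorm(prod(sh)), dim = sh)
    tex <- array(cpp_gauss3(as.numeric(tex), sh, c(3, 3, 3)), dim = sh)
    tex <- tex / sd(tex) * spec$texture_sd
    soft_only <- body & !column & !airway & !oral & !mandible &
      !Reduce(`|`, marker_masks)
    vol[soft_only] <- vol[soft_only] + tex[soft_only]
    # mild anti-aliasing blur + faint noise
    vol <- array(cpp_gauss3(as.numeric(vol), sh, c(0.7, 0.7, 0.7)), dim = sh)
    if (spec$noise_sd > 0) vol <- vol + rnorm(prod(sh), sd = spec$noise_sd)
    img <- image3d(vol, spec$spacing, c(0, 0, 0))
    organs <- list(larynx = larynx & !airway, spinal_cord = cord,
                   oral_cavity = oral, mandible = mandible,
                   parotid = parotid)
    masks <- c(organs, marker_masks)
    masks <- lapply(masks, function(m) binary_mask(m, spec$spacing, c(0, 0, 0)))
    for (nm in names(masks))
      if (sum(masks[[nm]]$voxels) == 0)
        stop("make_phantom: structure ", nm, " does not fit the requested shape")
    cents <- vapply(masks[paste0("P", seq_along(marker_z))], marker_centroid,
                    numeric(3))
    landmarks <- landmark_set(colnames(cents), cents[1, ], cents[2, ], cents[3, ])
    list(image = img, masks = masks, landmarks = landmarks,
         body = binary_mask(body, spec$spacing, c(0, 0, 0)))
  })
}

#' Random smooth invertible ground-truth warp
#'
#' A cubic B-spline field whose control displacements are drawn uniformly
#' from `[-max_disp, max_disp]^3`.  The constraint
#' `max_disp <= 0.4 * cp_spacing` keeps the field diffeomorphic in
#' practice; the numerical Jacobian is checked and the draw repeated (up
#' to 10 times) if it ever fails.
#'
#' @param fixed [image3d()] giving the grid.
#' @param cp_spacing_mm control-point spacing (mm).
#' @param max_disp_mm maximum control displacement per component (mm).
#' @param seed RNG seed.
#' @return A [displacement_field()] with `min det(I + grad u) > 0`.
#' @export
make_ground_truth_warp <- function(fixed, cp_spacing_mm = 32,
                                   max_disp_mm = 8, seed = 1) {
  if (max_disp_mm > 0.4 * cp_spacing_mm)
    stop("make_ground_truth_warp: need max_disp_mm <= 0.4 * cp_spacing_mm")
  if (max_disp_mm == 0) return(zero_field(fixed))
  with_seed(seed, {
    grid <- make_control_grid(fixed, cp_spacing_mm)
    for (try in 1:10) {
      grid$displacements[] <- runif(length(grid$displacements),
                                    -max_disp_mm, max_disp_mm)
      u <- evaluate_ffd(grid, fixed)
      if (min(jacobian_determinant(u)$voxels) > 0) return(u)
    }
    stop("make_ground_truth_warp: no invertible draw in 10 attempts")
  })
}

#' CBCT-style degradation configuration
#'
#' Defaults are calibrated so that NCC(clean, degraded) lands in the
#' 0.6-0.9 band on the default phantom: strong enough that direct
#' intensity comparison (SSD) is defeated, weak enough that MI-driven
#' registration still converges.
#'
#' @param gamma exponent of the monotone intensity remap on the
#'   [0, 1]-normalized scale.
#' @param contrast multiplicative rescaling of the remapped range.
#' @param shading peak relative amplitude of the multiplicative
#'   low-frequency shading field.
#' @param shading_sigma_vox smoothness (voxels) of the shading field.
#' @param noise_sd additive Gaussian noise as a fraction of the intensity
#'   range.
#' @export
degrade_config <- function(gamma = 0.5, contrast = 0.85, shading = 0.15,
                           shading_sigma_vox = 16, noise_sd = 0.03) {
  list(gamma = gamma, contrast = contrast, shading = shading,
       shading_sigma_vox = shading_sigma_vox, noise_sd = noise_sd)
}

#' Apply a CBCT-like intensity degradation
#'
#' A strictly monotone nonlinear remap (gamma curve on the normalized
#' intensity scale), a multiplicative low-frequency shading field, and
#' additive Gaussian noise.  The rank order of tissue-class mean
#' intensities is preserved, but the voxelwise intensity relationship to
#' the input becomes nonlinear and spatially varying, which is what makes
#' the mutual-information objective necessary.
#'
#' @param img clean [image3d()].
#' @param seed RNG seed.
#' @param cfg a [degrade_config()]; `gamma = 1, shading = 0, noise_sd = 0,
#'   contrast = 1` is the identity.
#' @return Degraded [image3d()] on the same grid.
#' @export
degrade_to_cbct <- function(img, seed = 1, cfg = degrade_config()) {
  with_seed(seed, {
    v <- img$voxels
    lo <- min(v); hi <- max(v); rng <- hi - lo
    if (rng == 0) rng <- 1
    t <- (v - lo) / rng
    t <- t^cfg$gamma
    out <- lo + t * rng * cfg$contrast
    if (cfg$shading > 0) {
      sh <- array(rnorm(prod(dim(v))), dim = dim(v))
      sh <- array(cpp_gauss3(as.numeric(sh), dim(v),
                             rep(cfg$shading_sigma_vox, 3)), dim = dim(v))
      sh <- sh / max(abs(sh)) * cfg$shading
      out <- (out - lo) * (1 + sh) + lo
    }
    if (cfg$noise_sd > 0)
      out <- out + rnorm(prod(dim(v)), sd = cfg$noise_sd * rng)
    image3d(out, img$spacing, img$origin)
  })
}

#' Generate a complete synthetic registration case
#'
#' The clean phantom plays the planning CT (moving image).  The fixed
#' (CBCT-like) image is the phantom warped by a random smooth ground-truth
#' field and then degraded; masks and markers are transported by the same
#' field, and the field itself is stored for scoring.
#'
#' @param spec a [phantom_spec()].
#' @param cp_spacing_mm,max_disp_mm ground-truth warp parameters.
#' @param degrade a [degrade_config()], or `NULL` for no degradation.
#' @param seed case seed (phantom, warp and degradation sub-seeds are
#'   derived from it).
#' @return A list of class `registration_case`: `fixed`, `moving`,
#'   `gt_field`, `masks_fixed`, `masks_moving`, `body_fixed`,
#'   `body_moving`, `landmarks_moving`.
#' @export
make_case <- function(spec = phantom_spec(), cp_spacing_mm = 32,
                      max_disp_mm = 8, degrade = degrade_config(),
                      seed = 1) {
  spec$seed <- seed
  ph <- make_phantom(spec)
  gt <- make_ground_truth_warp(ph$image, cp_spacing_mm, max_disp_mm,
                               seed = seed + 1000L)
  fixed_clean <- apply_warp(ph$image, gt, "linear")
  fixed <- if (is.null(degrade)) fixed_clean
           else degrade_to_cbct(fixed_clean, seed = seed + 2000L, cfg = degrade)
  masks_fixed <- lapply(ph$masks, warp_mask, field = gt)
  structure(list(fixed = fixed, moving = ph$image, gt_field = gt,
                 masks_fixed = masks_fixed, masks_moving = ph$masks,
                 body_fixed = warp_mask(ph$body, gt), body_moving = ph$body,
                 landmarks_moving = ph$landmarks, seed = seed),
            class = "registration_case")
}
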