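#' Gaussian multi-resolution pyramid
#'
#' Level 1 is the full-resolution image; each coarser level is Gaussian
#' smoothed (sigma = 1 voxel) and downsampled by 2 per axis with doubled
#' spacing.
#'
#' @param img an [image3d()].
#' @param levels pyramid depth (>= 1); the coarsest level must keep at
#'   least 8 voxels per axis.
#' @return List of [image3d()]s, fine to coarse.
#' @export
build_pyramid <- function(img, levels) {
  stopifnot(levels >= 1)
  if (any(floor((grid_dim(img) - 1) / 2^(levels - 1)) + 1 < 8))
    stop("build_pyramid: image too small for ", levels, " levels (needs >= 8 voxels per axis at the coarsest)")
  out <- vector("list", levels)
  out[[1]] <- img
  cur <- img
  for (l in seq_len(levels - 1)) {
    d <- grid_dim(cur)
    sm <- array(cpp_gauss3(as.numeric(cur$voxels), d, c(1, 1, 1)), dim = d)
    keep <- lapply(d, function(n) seq(1, n, by = 2))
    cur <- image3d(sm[keep[[1]], keep[[2]], keep[[3]], drop = FALSE],
                   cur$spacing * 2, cur$origin)
    out[[l + 1]] <- cur
  }
  out
}

#' Transfer a displacement field to a finer grid
#'
#' Trilinear interpolation of each component onto the target grid; the
#' vectors stay in mm, so no rescaling is involved.
#'
#' @param u a [displacement_field()] on a coarse grid.
#' @param target [image3d()] with the finer grid.
#' @return A [displacement_field()] on `target`'s grid.
#' @export
upsample_field <- function(u, target) {
  stopifnot(inherits(u, "dispfield"), inherits(target, "image3d"))
  d <- grid_dim(target)
  idx <- grid_indices(d)
  ud <- grid_dim(u)
  xi <- (target$origin[1] + idx$ix * target$spacing[1] - u$origin[1]) / u$spacing[1]
  yi <- (target$origin[2] + idx$iy * target$spacing[2] - u$origin[2]) / u$spacing[2]
  zi <- (target$origin[3] + idx$iz * target$spacing[3] - u$origin[3]) / u$spacing[3]
  out <- array(0, dim = c(d, 3L))
  for (c in 1:3) {
    s <- cpp_interp3(as.numeric(u$vectors[, , , c]), ud, xi, yi, zi, 2L, 0)
    out[, , , c] <- array(s, dim = d)
  }
  displacement_field(out, target$spacing, target$origin)
}

#' Pipeline configuration
#'
#' @param levels pyramid depth (default 3, the conventional multi-scale
#'   depth for CT/CBCT registration).
#' @param mode `"hybrid"` (FFD initial estimate + fluid refinement) or
#'   `"ffd_only"` (the FFD baseline used for ablation).
#' @param ffd_levels how many of the coarsest levels run the FFD stage;
#'   `NULL` = all levels (both modes), so the hybrid is the FFD baseline
#'   plus interleaved fluid refinement.
#' @param cp_spacing_mm control-point spacing at full resolution (doubled
#'   per coarser level); `NULL` = 5 mm.
#' @param ffd an [ffd_config()].
#' @param fluid a [fluid_config()]; `max_iter = 0` disables the fluid
#'   stage (which makes hybrid identical to ffd_only at equal
#'   `ffd_levels`).
#' @param ffd_max_iter FFD iteration cap per level.
#' @param seed retained for provenance; the pipeline itself is
#'   deterministic.
#' @export
pipeline_config <- function(levels = 3, mode = c("hybrid", "ffd_only"),
                            ffd_levels = NULL, cp_spacing_mm = NULL,
                            ffd = ffd_config(), fluid = fluid_config(),
                            ffd_max_iter = 30, seed = 0) {
  mode <- match.arg(mode)
  stopifnot(levels >= 1)
  list(levels = levels, mode = mode, ffd_levels = ffd_levels,
       cp_spacing_mm = cp_spacing_mm, ffd = ffd, fluid = fluid,
       ffd_max_iter = ffd_max_iter, seed = seed)
}

#' Hybrid FFD + viscous-fluid registration
#'
#' Orchestrates the coarse-to-fine pipeline: a Gaussian pyramid is built
#' for both images; on the coarsest levels a sparse-control-point B-spline
#' FFD provides the initial warp estimate, which the viscous-fluid stage
#' then refines to a dense per-voxel field (on every level, in hybrid
#' mode).  The final full-resolution field, the warped moving image, and a
#' report with before/after similarity metrics are returned.
#'
#' @param fixed reference [image3d()] (the CBCT-like image).
#' @param moving [image3d()] to deform (the pCT-like image).  If its grid
#'   differs from `fixed`'s it is resampled with a warning.
#' @param cfg a [pipeline_config()].
#' @return A list of class `hybridreg_result`: `field`, `warped`,
#'   `report` (list with metrics before/after and per-level traces).
#' @export
register_hybrid <- function(fixed, moving, cfg = pipeline_config()) {
  stopifnot(inherits(fixed, "image3d"), inherits(moving, "image3d"))
  if (!same_grid(fixed, moving)) {
    warning("register_hybrid: moving resampled onto the fixed grid")
    moving <- resample_to_grid(moving, fixed)
  }
  levels <- cfg$levels
  fp <- build_pyramid(fixed, levels)
  mp <- build_pyramid(moving, levels)
  n_ffd <- if (!is.null(cfg$ffd_levels)) cfg$ffd_levels else levels
  metrics_before <- case_metrics(fixed, moving)
  u <- NULL
  traces <- list()
  for (l in seq(levels, 1)) {
    f_l <- fp[[l]]; m_l <- mp[[l]]
    u <- if (is.null(u)) zero_field(f_l) else upsample_field(u, f_l)
    run_ffd <- (levels - l + 1) <= n_ffd
    if (run_ffd) {
      cp <- ffd_cp_spacing(cfg, fp, l, levels)
      m_w <- apply_warp(m_l, u, "linear")
      grid <- make_control_grid(f_l, cp)
      grid <- optimize_ffd_level(f_l, m_w, grid, max_iter = cfg$ffd_max_iter,
                                 config = cfg$ffd)
      u <- compose_fields(u, evaluate_ffd(grid, f_l))
      traces[[paste0("level", l, "_ffd")]] <- attr(grid, "trace")
    }
    if (cfg$mode == "hybrid" && cfg$fluid$max_iter > 0) {
      res <- fluid_stage(f_l, m_l, u, cfg$fluid)
      u <- res$field
      traces[[paste0("level", l, "_fluid")]] <- res$trace
    }
    if (any(!is.finite(u$vectors)))
      stop("register_hybrid: non-finite field at level ", l)
  }
  warped <- apply_warp(moving, u, "linear")
  report <- list(mode = cfg$mode, levels = levels,
                 metrics_before = metrics_before,
                 metrics_after = case_metrics(fixed, warped),
                 min_jacobian = min(jacobian_determinant(u)$voxels),
                 traces = traces)
  structure(list(field = u, warped = warped, report = report),
            class = "hybridreg_result")
}

ffd_cp_spacing <- function(cfg, pyramid, l, levels) {
  base <- if (is.null(cfg$cp_spacing_mm)) 5 else cfg$cp_spacing_mm
  rep_len(base * 2^(l - 1), 3L)
}

case_metrics <- function(fixed, warped, bins = 64) {
  list(mi = mi_metric(fixed, warped, bins),
       ncc = ncc(fixed, warped),
       mean_abs_diff = mean_abs_diff(fixed, warped))
}

#' @export
print.hybridreg_result <- function(x, ...) {
  b <- x$report$metrics_before; a <- x$report$metrics_after
  cat(sprintf("<hybridreg_result> mode %s, %d levels\n", x$report$mode,
              x$report$levels))
  cat(sprintf("  MI   %.4f -> %.4f\n  NCC  %.4f -> %.4f\n  MAD  %.4g -> %.4g\n",
              b$mi, a$mi, b$ncc, a$ncc, b$mean_abs_diff, a$mean_abs_diff))
  cat(sprintf("  min Jacobian %.3f, max |u| %.2f mm\n",
              x$report$min_jacobian, max(field_magnitude(x$field))))
  invisible(x)
}

#' Integer-voxel translation pre-alignment
#'
#' Exhaustive search over a bounded window for the integer-voxel
#' translation of `moving` maximizing NCC with `fixed`.  This is a
#' convenience stand-in for the rigid pre-registration the pipeline
#' otherwise assumes has been done upstream.
#'
#' @param fixed,moving [image3d()]s on the same grid.
#' @param max_shift search window half-width in voxels per axis.
#' @return The translated moving [image3d()], with attributes
#'   `shift_voxels` (the applied integer shift), `ncc`, and `degenerate`
#'   (TRUE when both images were constant and no shift was identifiable).
#' @export
pre_translate <- function(fixed, moving, max_shift = 10) {
  if (!same_grid(fixed, moving)) stop_grid_mismatch("pre_translate", fixed, moving)
  d <- grid_dim(fixed)
  if (any(2 * max_shift + 1 > d))
    stop("pre_translate: search window exceeds the image size")
  r <- cpp_best_shift(as.numeric(fixed$voxels), as.numeric(moving$voxels),
                      d, as.integer(max_shift))
  degen <- r[5] == 1
  if (degen) {
    warning("pre_translate: constant image(s); returning zero translation")
    shift <- c(0L, 0L, 0L)
  } else shift <- as.integer(r[1:3])
  u <- zero_field(fixed)
  for (c in 1:3) u$vectors[, , , c] <- -shift[c] * fixed$spacing[c]
  out <- apply_warp(moving, u, "linear")
  attr(out, "shift_voxels") <- shift
  attr(out, "ncc") <- if (degen) NA_real_ else r[4]
  attr(out, "degenerate") <- degen
  out
}
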