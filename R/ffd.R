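#' Create a zero-displacement B-spline control grid
#'
#' The lattice covers the image's physical extent plus the margin required
#' by cubic B-spline support: `ceil(extent / cp_spacing) + 3` points per
#' axis, with the lattice origin one control spacing before the image
#' origin.
#'
#' @param fixed [image3d()] whose domain the grid must cover.
#' @param cp_spacing length-3 (or scalar) control-point spacing in mm;
#'   must be positive and smaller than the image extent on every axis.
#' @return An object of class `cpgrid` with fields `displacements`
#'   (ncx, ncy, ncz, 3 array, mm), `cp_spacing`, `cp_origin`.
#' @export
make_control_grid <- function(fixed, cp_spacing) {
  cp_spacing <- rep_len(as.numeric(cp_spacing), 3L)
  if (any(cp_spacing <= 0)) stop("make_control_grid: cp_spacing must be > 0")
  ext <- grid_extent(fixed)
  if (any(cp_spacing >= ext))
    stop(sprintf("make_control_grid: cp_spacing (%s mm) must be smaller than the image extent (%s mm)",
                 paste(signif(cp_spacing, 4), collapse = "x"),
                 paste(signif(ext, 4), collapse = "x")))
  ncp <- as.integer(ceiling(ext / cp_spacing)) + 3L
  structure(list(displacements = array(0, dim = c(ncp, 3L)),
                 cp_spacing = cp_spacing,
                 cp_origin = fixed$origin - cp_spacing),
            class = "cpgrid")
}

#' @export
print.cpgrid <- function(x, ...) {
  cat(sprintf("<cpgrid> %s control points, spacing %s mm, max |c| %.3g mm\n",
              paste(dim(x$displacements)[1:3], collapse = "x"),
              paste(signif(x$cp_spacing, 4), collapse = "x"),
              max(abs(x$displacements))))
  invisible(x)
}

# check that the lattice covers every voxel of img with full cubic support
check_coverage <- function(grid, img) {
  ncp <- dim(grid$displacements)[1:3]
  for (ax in 1:3) {
    g0 <- (img$origin[ax] - grid$cp_origin[ax]) / grid$cp_spacing[ax]
    g1 <- g0 + grid_extent(img)[ax] / grid$cp_spacing[ax]
    if (floor(g0) < 1 - 1e-9 || g1 > ncp[ax] - 2 + 1e-9)
      stop("evaluate_ffd: control grid does not cover the image domain on axis ", ax)
  }
  invisible(TRUE)
}

#' Evaluate a B-spline FFD as a dense displacement field
#'
#' `u(x)` is the tensor-product cubic B-spline interpolation of the
#' control-point displacements: a weighted sum over the 4x4x4 lattice
#' neighbourhood of `x`, with weights from its fractional lattice
#' coordinate.  The weights form a partition of unity, so a lattice of
#' equal displacements evaluates to that constant field.
#'
#' @param grid a `cpgrid` from [make_control_grid()].
#' @param fixed [image3d()] giving the evaluation grid.
#' @return A [displacement_field()] on `fixed`'s grid.
#' @export
evaluate_ffd <- function(grid, fixed) {
  stopifnot(inherits(grid, "cpgrid"))
  check_coverage(grid, fixed)
  d <- grid_dim(fixed)
  v <- cpp_ffd_eval(as.numeric(grid$displacements),
                    dim(grid$displacements)[1:3],
                    grid$cp_origin, grid$cp_spacing,
                    d, fixed$spacing, fixed$origin)
  displacement_field(array(v, dim = c(d, 3L)), fixed$spacing, fixed$origin)
}

#' FFD optimizer configuration
#'
#' @param bins histogram bins for the MI objective (`NULL` = adaptive,
#'   `cbrt(n_voxels)` clamped to `[16, 64]`).
#' @param parzen_sigma_bins Parzen smoothing of the joint histogram (bins).
#' @param step0_rel initial line-search step as a fraction of the minimum
#'   control-point spacing.
#' @param armijo_max halvings attempted before declaring no improvement.
#' @param plateau_tol,plateau_window stop when the relative MI improvement
#'   over `plateau_window` accepted iterations falls below `plateau_tol`.
#' @param bending_weight optional bending-energy penalty weight (0 = off,
#'   the default; smoothness normally comes from control-point sparsity).
#' @param accept_k scale of the minimum accepted MI improvement,
#'   `accept_k * bins^2 / n` nats -- the statistical resolution of an
#'   n-sample, bins^2-cell histogram.  Gains below it are overfitting
#'   creep (they let a registered pair drift); gains of genuine alignment
#'   are far larger.
#' @export
ffd_config <- function(bins = NULL, parzen_sigma_bins = 1, step0_rel = 0.4,
                       armijo_max = 8, plateau_tol = 1e-4,
                       plateau_window = 5, bending_weight = 0,
                       accept_k = 0.05) {
  list(bins = bins, parzen_sigma_bins = parzen_sigma_bins,
       step0_rel = step0_rel, armijo_max = armijo_max,
       plateau_tol = plateau_tol, plateau_window = plateau_window,
       bending_weight = bending_weight, accept_k = accept_k)
}

adaptive_bins <- function(n) as.integer(min(64, max(16, round(n^(1 / 3)))))

#' Serialize / restore a control grid
#'
#' JSON with the lattice geometry and the displacement array flattened in
#' column-major order (lattices are small, so no binary sidecar is
#' needed).
#'
#' @param grid a `cpgrid`.
#' @param path output / input `.json` file.
#' @return `write_control_grid` the path, `read_control_grid` a `cpgrid`.
#' @export
write_control_grid <- function(grid, path) {
  stopifnot(inherits(grid, "cpgrid"))
  jsonlite::write_json(list(ncp = dim(grid$displacements)[1:3],
                            cp_spacing = grid$cp_spacing,
                            cp_origin = grid$cp_origin,
                            displacements = as.numeric(grid$displacements)),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_control_grid
#' @export
read_control_grid <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(displacements = array(j$displacements, dim = c(j$ncp, 3L)),
                 cp_spacing = j$cp_spacing, cp_origin = j$cp_origin),
            class = "cpgrid")
}

# discrete bending-energy penalty: sum of squared second differences of
# the control lattice (per mm^2), optional
bending_penalty <- function(disp, cp_spacing) {
  pen <- 0
  for (ax in 1:3) {
    n <- dim(disp)[ax]
    if (n < 3) next
    idx <- function(i) switch(ax, disp[i, , , , drop = FALSE],
                              disp[, i, , , drop = FALSE],
                              disp[, , i, , drop = FALSE])
    d2 <- (idx(3:n) - 2 * idx(2:(n - 1)) + idx(1:(n - 2))) / cp_spacing[ax]^2
    pen <- pen + sum(d2^2)
  }
  pen
}

#' Optimize one FFD level by gradient ascent on mutual information
#'
#' The gradient of MI with respect to each control displacement is the
#' B-spline-weighted aggregation of the per-voxel MI force; ascent uses an
#' Armijo-style backtracking line search, stopping at `max_iter`, when no
#' backtracked step improves MI, or when the MI improvement plateaus.
#'
#' @param fixed,moving [image3d()]s on the same grid (`moving` already
#'   carries any warp from previous levels).
#' @param grid initial `cpgrid` (typically all zeros).
#' @param max_iter iteration cap (default 30, the conventional multi-scale
#'   setting for this problem).
#' @param config an [ffd_config()].
#' @return The optimized `cpgrid`, with an attached `trace` attribute
#'   (data.frame: iteration, mi, step_mm).
#' @export
optimize_ffd_level <- function(fixed, moving, grid, max_iter = 30,
                               config = ffd_config()) {
  if (!same_grid(fixed, moving)) stop_grid_mismatch("optimize_ffd_level", fixed, moving)
  bins <- if (is.null(config$bins)) adaptive_bins(length(fixed$voxels)) else config$bins
  rf <- intensity_window(fixed)
  rm_ <- intensity_window(moving)
  fvec <- as.vector(fixed$voxels)
  bg <- min(moving$voxels)
  objective <- function(disp) {
    g2 <- grid; g2$displacements <- disp
    u <- evaluate_ffd(g2, fixed)
    w <- apply_warp(moving, u, "linear", background = bg)
    wv <- as.vector(w$voxels)
    mi <- smoothed_mi(fvec, wv, bins, rf, rm_, config$parzen_sigma_bins)
    pv <- smoothed_mi_pv(fvec, wv, bins, rf, rm_, config$parzen_sigma_bins)
    if (config$bending_weight > 0) {
      pen <- config$bending_weight * bending_penalty(disp, grid$cp_spacing)
      mi <- mi - pen
      pv <- pv - pen
    }
    list(mi = mi, pv = pv, warped = w)
  }
  tau <- max(1e-7, config$accept_k * bins^2 / length(fixed$voxels))
  disp <- grid$displacements
  cur <- objective(disp)
  trace <- data.frame(iteration = 0L, mi = cur$mi, step_mm = 0)
  step0 <- config$step0_rel * min(grid$cp_spacing)
  for (it in seq_len(max_iter)) {
    Fv <- mi_force(fixed, cur$warped, bins = bins,
                   parzen_sigma_bins = config$parzen_sigma_bins,
                   range_fixed = rf, range_moving = rm_)
    g <- cpp_ffd_scatter(as.numeric(Fv$vectors),
                         dim(disp)[1:3], grid$cp_origin, grid$cp_spacing,
                         grid_dim(fixed), fixed$spacing, fixed$origin)
    if (any(!is.finite(g)))
      stop("optimize_ffd_level: non-finite MI gradient at iteration ", it)
    gmax <- max(abs(g))
    if (gmax == 0) break
    dir <- array(g / gmax, dim = dim(disp))
    step <- step0
    accepted <- FALSE
    for (k in seq_len(config$armijo_max)) {
      trial <- objective(disp + step * dir)
      if (trial$mi > cur$mi + tau && trial$pv > cur$pv + tau) {
        disp <- disp + step * dir
        cur <- trial
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break  # the cost function cannot be further improved
    trace <- rbind(trace, data.frame(iteration = it, mi = cur$mi, step_mm = step))
    w <- config$plateau_window
    if (nrow(trace) > w) {
      prev <- trace$mi[nrow(trace) - w]
      if ((cur$mi - prev) < config$plateau_tol * max(abs(prev), 1e-8)) break
    }
  }
  grid$displacements <- disp
  attr(grid, "trace") <- trace
  grid
}
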