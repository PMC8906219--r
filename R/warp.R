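#' Warp an image with a displacement field (backward mapping)
#'
#' Produces an image on the field's (fixed) grid whose value at voxel
#' position `x` is the moving image sampled at physical position
#' `x + u(x)`.  Samples falling outside the moving image's extent take the
#' background value.
#'
#' @param moving an [image3d()] (any grid sharing the physical space).
#' @param field a [displacement_field()] on the output (fixed) grid.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param background intensity for out-of-domain samples; default the
#'   minimum of `moving` (air, for CT-like volumes).
#' @return The warped [image3d()] on the field's grid.
#' @export
apply_warp <- function(moving, field, interpolation = c("linear", "nearest"),
                       background = NULL) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(moving, "image3d") || inherits(moving, "binmask"),
            inherits(field, "dispfield"))
  if (is.null(background)) background <- min(moving$voxels)
  d <- grid_dim(field)
  idx <- grid_indices(d)
  v <- field$vectors
  px <- field$origin[1] + idx$ix * field$spacing[1] + as.vector(v[, , , 1])
  py <- field$origin[2] + idx$iy * field$spacing[2] + as.vector(v[, , , 2])
  pz <- field$origin[3] + idx$iz * field$spacing[3] + as.vector(v[, , , 3])
  xi <- (px - moving$origin[1]) / moving$spacing[1]
  yi <- (py - moving$origin[2]) / moving$spacing[2]
  zi <- (pz - moving$origin[3]) / moving$spacing[3]
  mode <- if (interpolation == "nearest") 1L else 0L
  out <- cpp_interp3(as.numeric(moving$voxels), grid_dim(moving),
                     xi, yi, zi, mode, as.numeric(background))
  image3d(array(out, dim = d), field$spacing, field$origin)
}

#' Propagate a binary mask through a displacement field
#'
#' Resamples the mask onto the field's grid; by default nearest-neighbour
#' so binarity is preserved without hidden smoothing, optionally trilinear
#' followed by a 0.5 threshold.
#'
#' @param mask a [binary_mask()] on the moving grid.
#' @param field a [displacement_field()] on the output grid.
#' @param method `"nearest"` (default) or `"linear_threshold"`.
#' @return A [binary_mask()] on the field's grid.
#' @export
warp_mask <- function(mask, field, method = c("nearest", "linear_threshold")) {
  method <- match.arg(method)
  stopifnot(inherits(mask, "binmask"))
  img <- image3d(array(as.numeric(mask$voxels), dim = dim(mask$voxels)),
                 mask$spacing, mask$origin)
  if (method == "nearest") {
    w <- apply_warp(img, field, "nearest", background = 0)
    binary_mask(w$voxels != 0, field$spacing, field$origin)
  } else {
    w <- apply_warp(img, field, "linear", background = 0)
    binary_mask(w$voxels >= 0.5, field$spacing, field$origin)
  }
}

#' Resample an image onto another image's grid
#'
#' Trilinear interpolation of `img` at the voxel positions of `target`
#' (used to bring the planning CT onto the CBCT grid before registration).
#'
#' @param img source [image3d()].
#' @param target [image3d()] providing spacing, origin and shape.
#' @param background value for target voxels outside `img`'s extent.
#' @return An [image3d()] on `target`'s grid.
#' @export
resample_to_grid <- function(img, target, background = NULL) {
  stopifnot(inherits(img, "image3d"), inherits(target, "image3d"))
  if (any(grid_dim(target) < 1L)) stop("resample_to_grid: degenerate target")
  apply_warp(img, zero_field(target), "linear", background = background)
}

# central differences along one axis of a 3D array, one-sided at the
# boundary faces; h = spacing (mm) along that axis
diff_axis <- function(a, axis, h) {
  n <- dim(a)[axis]
  d <- array(0, dim = dim(a))
  if (n < 2) return(d)
  ip <- function(i) switch(axis,
                           a[i, , , drop = FALSE],
                           a[, i, , drop = FALSE],
                           a[, , i, drop = FALSE])
  assign_ax <- function(i, val) {
    if (axis == 1) d[i, , ] <<- val
    else if (axis == 2) d[, i, ] <<- val
    else d[, , i] <<- val
  }
  if (n > 2) assign_ax(2:(n - 1), (ip(3:n) - ip(1:(n - 2))) / (2 * h))
  assign_ax(1, (ip(2) - ip(1)) / h)
  assign_ax(n, (ip(n) - ip(n - 1)) / h)
  d
}

#' Jacobian determinant map of a displacement field
#'
#' Computes `det(I + grad u)` per voxel with central differences in
#' physical units (mm/mm), one-sided at the boundary.  Values below zero
#' indicate folding (loss of topology); the fluid stage monitors this map
#' for its regridding safeguard.
#'
#' @param field a [displacement_field()] with at least 2 voxels per axis.
#' @return An [image3d()] of determinants on the same grid.
#' @export
jacobian_determinant <- function(field) {
  stopifnot(inherits(field, "dispfield"))
  d <- grid_dim(field)
  if (any(d < 2L)) stop("jacobian_determinant: field must be >= 2 voxels per axis")
  g <- vector("list", 9)
  for (ci in 1:3) for (ax in 1:3) {
    g[[(ci - 1) * 3 + ax]] <- diff_axis(field$vectors[, , , ci], ax,
                                        field$spacing[ax])
  }
  # J[i,j] = d u_i / d x_j ; det(I + J)
  a11 <- 1 + g[[1]]; a12 <- g[[2]]; a13 <- g[[3]]
  a21 <- g[[4]]; a22 <- 1 + g[[5]]; a23 <- g[[6]]
  a31 <- g[[7]]; a32 <- g[[8]]; a33 <- 1 + g[[9]]
  det <- a11 * (a22 * a33 - a23 * a32) -
         a12 * (a21 * a33 - a23 * a31) +
         a13 * (a21 * a32 - a22 * a31)
  image3d(det, field$spacing, field$origin)
}

#' Compose two backward displacement fields
#'
#' Returns the field of the composite warp "first apply `outer`, then
#' sample through `inner`": `u(x) = inner(x) + outer(x + inner(x))`, so that
#' warping with the result equals warping with `outer` followed by warping
#' the result with `inner`.  Both fields must live on the same grid;
#' `outer` is resampled with edge clamping.
#'
#' @param outer,inner [displacement_field()]s on the same grid.
#' @return A [displacement_field()].
#' @export
compose_fields <- function(outer, inner) {
  stopifnot(inherits(outer, "dispfield"), inherits(inner, "dispfield"))
  if (!same_grid(outer, inner)) stop_grid_mismatch("compose_fields", outer, inner)
  d <- grid_dim(inner)
  idx <- grid_indices(d)
  xi <- idx$ix + as.vector(inner$vectors[, , , 1]) / inner$spacing[1]
  yi <- idx$iy + as.vector(inner$vectors[, , , 2]) / inner$spacing[2]
  zi <- idx$iz + as.vector(inner$vectors[, , , 3]) / inner$spacing[3]
  out <- array(0, dim = c(d, 3L))
  for (c in 1:3) {
    s <- cpp_interp3(as.numeric(outer$vectors[, , , c]), d, xi, yi, zi, 2L, 0)
    out[, , , c] <- inner$vectors[, , , c] + array(s, dim = d)
  }
  displacement_field(out, inner$spacing, inner$origin)
}
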