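#' 3D scalar image
#'
#' The unit every registration operation works on: a 3D array of
#' intensities plus the voxel spacing (mm) and origin (mm) tying voxel
#' indices to physical space.  Voxel index `i` (0-based) sits at physical
#' position `origin + i * spacing`; displacements are always stored in mm,
#' never in voxels.
#'
#' @param voxels 3D numeric array of intensities (arbitrary units).
#' @param spacing length-3 positive numeric, mm per voxel.
#' @param origin length-3 numeric, mm position of voxel (0,0,0).
#' @return An object of class `image3d`.
#' @export
image3d <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("image3d: voxels must be a 3D array, got ",
         length(dim(voxels)), " dimensions")
  if (any(dim(voxels) < 1L)) stop("image3d: every dimension must be >= 1")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image3d: spacing must be 3 positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("image3d: origin must be 3 finite numbers")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image3d")
}

#' @export
print.image3d <- function(x, ...) {
  cat(sprintf("<image3d> %s voxels, spacing %s mm, origin %s mm, range [%g, %g]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ","),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary mask on an image grid
#'
#' @param voxels 3D array with values in \{0, 1\} (logical accepted).
#' @param spacing,origin geometry, as [image3d()].
#' @return An object of class `binmask`.
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  storage.mode(voxels) <- "integer"
  if (length(dim(voxels)) != 3L) stop("binary_mask: voxels must be a 3D array")
  if (!all(voxels %in% c(0L, 1L)))
    stop("binary_mask: values must be 0 or 1")
  img <- image3d(array(1, dim = dim(voxels)), spacing, origin)  # geometry checks
  structure(list(voxels = voxels, spacing = img$spacing, origin = img$origin),
            class = "binmask")
}

#' @export
print.binmask <- function(x, ...) {
  cat(sprintf("<binmask> %s voxels, %d foreground, spacing %s mm\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Dense displacement field
#'
#' Per-voxel 3-vectors in mm, defined on the fixed-image grid.  The field
#' maps fixed-space positions into moving-space sampling positions
#' (backward warping): the warped image at voxel position `x` is the moving
#' image sampled at `x + u(x)`.
#'
#' @param vectors 4D numeric array `(nx, ny, nz, 3)` of mm displacements.
#' @param spacing,origin geometry of the fixed grid.
#' @return An object of class `dispfield`.
#' @export
displacement_field <- function(vectors, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0)) {
  vectors <- as.array(vectors)
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement_field: vectors must be an (nx, ny, nz, 3) array, got ",
         paste(d, collapse = "x"))
  if (any(!is.finite(vectors)))
    stop("displacement_field: field contains non-finite values")
  img <- image3d(array(0, dim = d[1:3]), spacing, origin)
  structure(list(vectors = vectors, spacing = img$spacing, origin = img$origin),
            class = "dispfield")
}

#' Zero displacement field on an image grid
#' @param img an [image3d()] giving the grid.
#' @return A [displacement_field()] of zeros.
#' @export
zero_field <- function(img) {
  displacement_field(array(0, dim = c(dim(img$voxels), 3L)),
                     img$spacing, img$origin)
}

#' @export
print.dispfield <- function(x, ...) {
  mag <- field_magnitude(x)
  cat(sprintf("<dispfield> %s grid, |u| mean %.3g mm, max %.3g mm\n",
              paste(dim(x$vectors)[1:3], collapse = "x"),
              mean(mag), max(mag)))
  invisible(x)
}

#' Per-voxel Euclidean magnitude of a displacement field (mm)
#' @param field a [displacement_field()].
#' @return 3D array of magnitudes.
#' @export
field_magnitude <- function(field) {
  v <- field$vectors
  sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)
}

#' Landmark set
#'
#' Labelled physical positions in mm, e.g. the five vertebral feature
#' points P1..P5 annotated on both images of a pair.
#'
#' @param label character vector of unique labels.
#' @param x,y,z numeric mm coordinates.
#' @return A `data.frame` of class `landmarks` with columns
#'   `label, x_mm, y_mm, z_mm`.
#' @export
landmark_set <- function(label = character(), x = numeric(),
                         y = numeric(), z = numeric()) {
  label <- as.character(label)
  if (anyDuplicated(label)) stop("landmark_set: labels must be unique")
  pos <- cbind(as.numeric(x), as.numeric(y), as.numeric(z))
  if (length(label) && any(!is.finite(pos)))
    stop("landmark_set: positions must be finite")
  out <- data.frame(label = label, x_mm = pos[, 1], y_mm = pos[, 2],
                    z_mm = pos[, 3], stringsAsFactors = FALSE)
  class(out) <- c("landmarks", "data.frame")
  out
}

# ---- internal geometry helpers ------------------------------------------

grid_dim <- function(x) if (inherits(x, "dispfield")) dim(x$vectors)[1:3] else dim(x$voxels)

same_grid <- function(a, b, tol = 1e-6) {
  identical(grid_dim(a), grid_dim(b)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_grid_mismatch <- function(what, a, b) {
  stop(sprintf("%s: grids differ (%s vs %s)", what,
               paste(grid_dim(a), collapse = "x"),
               paste(grid_dim(b), collapse = "x")), call. = FALSE)
}

# 0-based voxel index arrays for a grid, as three long vectors.
grid_indices <- function(d) {
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  list(ix = rep.int(seq_len(nx) - 1L, ny * nz),
       iy = rep.int(rep(seq_len(ny) - 1L, each = nx), nz),
       iz = rep(seq_len(nz) - 1L, each = nx * ny))
}

# physical extent (mm) spanned by voxel centres along each axis
grid_extent <- function(img) (grid_dim(img) - 1) * img$spacing
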