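#' Dice similarity coefficient
#'
#' `DSC(A, B) = 2 |A intersect B| / (|A| + |B|)` over full voxel sets.
#'
#' @param a,b [binary_mask()]s on the same grid; at least one non-empty.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  if (!same_grid(a, b)) stop_grid_mismatch("dsc", a, b)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0) stop("dsc: both masks are empty (undefined)")
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

# physical coordinates (mm) of the surface voxels of a mask: members with
# at least one non-member 6-neighbour (faces of the array count as outside)
surface_points <- function(mask) {
  v <- mask$voxels
  d <- dim(v)
  pad <- array(0L, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] +
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] +
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] +
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] +
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] +
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  surf <- which(v == 1L & nb < 6L, arr.ind = TRUE)
  cbind(mask$origin[1] + (surf[, 1] - 1) * mask$spacing[1],
        mask$origin[2] + (surf[, 2] - 1) * mask$spacing[2],
        mask$origin[3] + (surf[, 3] - 1) * mask$spacing[3])
}

#' Directed Hausdorff distance between two masks (mm)
#'
#' `HD(A, B) = max_{a in A} min_{b in B} d(a, b)` computed between the
#' surface voxel sets of the two masks (members with a non-member
#' 6-neighbour), with distances in physical mm.
#'
#' @param a,b non-empty [binary_mask()]s.
#' @return Distance in mm.
#' @export
hausdorff_directed <- function(a, b) {
  if (sum(a$voxels) == 0 || sum(b$voxels) == 0)
    stop("hausdorff_directed: empty mask")
  cpp_hausdorff_directed(surface_points(a), surface_points(b))
}

#' Symmetric Hausdorff distance (mm)
#'
#' `max(HD(A, B), HD(B, A))`; the headline HD value of a report.
#'
#' @inheritParams hausdorff_directed
#' @export
hausdorff <- function(a, b) {
  max(hausdorff_directed(a, b), hausdorff_directed(b, a))
}

#' Centroid of a mask in physical coordinates (mm)
#'
#' Intensity-unweighted mean of the member voxels' positions; the marker
#' position of a small-circle annotation.
#'
#' @param mask non-empty [binary_mask()].
#' @return Length-3 numeric, mm.
#' @export
marker_centroid <- function(mask) {
  w <- which(mask$voxels == 1L, arr.ind = TRUE)
  if (nrow(w) == 0) stop("marker_centroid: empty mask")
  unname(mask$origin + (colMeans(w) - 1) * mask$spacing)
}

#' Centroid target registration error (mm)
#'
#' Euclidean distance between the centroid of the moving marker propagated
#' through the field and the centroid of the fixed marker.
#'
#' @param marker_moving,marker_fixed non-empty [binary_mask()]s.
#' @param field [displacement_field()] on the fixed grid.
#' @return TRE in mm.
#' @export
tre <- function(marker_moving, marker_fixed, field) {
  w <- warp_mask(marker_moving, field)
  if (sum(w$voxels) == 0)
    stop("tre: warped marker is empty (degenerate warp)")
  sqrt(sum((marker_centroid(w) - marker_centroid(marker_fixed))^2))
}

#' Paired two-sided t-test
#'
#' Classic paired t on `d = x - y` with `n - 1` degrees of freedom; the
#' p-value comes from the regularized incomplete beta function
#' (`pbeta(df / (df + t^2), df / 2, 1 / 2)`), equivalent to the Student-t
#' tail formula.
#'
#' @param x,y equal-length numeric vectors, `n >= 2`.
#' @return List `(t, p, df, mean_diff)`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired_t_test: lengths differ")
  n <- length(x)
  if (n < 2) stop("paired_t_test: need n >= 2 pairs")
  d <- x - y
  s <- sd(d)
  if (!is.finite(s) || s == 0)
    stop("paired_t_test: zero variance of differences")
  t <- mean(d) / (s / sqrt(n))
  df <- n - 1
  p <- pbeta(df / (df + t^2), df / 2, 0.5)
  list(t = t, p = p, df = df, mean_diff = mean(d))
}

#' Assemble the full evaluation report for one registered case
#'
#' Computes the intensity metrics (MI, NCC, mean absolute difference) over
#' the case, DSC plus directed/symmetric Hausdorff distance per propagated
#' structure, and centroid TRE per marker pair (before = zero field, after
#' = the recovered field).  A structure or marker missing on either side is
#' flagged in its row; the remaining rows are still computed.
#'
#' @param fixed reference [image3d()].
#' @param warped warped moving [image3d()] on the fixed grid.
#' @param structure_pairs named list; each element a list with elements
#'   `fixed` and `moving` ([binary_mask()]s, either may be `NULL`).
#' @param marker_pairs named list with the same shape, for point markers.
#' @param field the recovered [displacement_field()].
#' @return A list of class `registration_report` with `metrics`,
#'   `structures` (data.frame: label, dsc, hd_fixed_to_moving,
#'   hd_moving_to_fixed, hd, status), `markers` (data.frame: label,
#'   tre_pre_mm, tre_post_mm, status), `min_jacobian`.
#' @export
evaluate_case <- function(fixed, warped, structure_pairs = list(),
                          marker_pairs = list(), field) {
  stopifnot(inherits(field, "dispfield"))
  metrics <- case_metrics(fixed, warped)
  srow <- function(label, pair) {
    if (is.null(pair$fixed) || is.null(pair$moving))
      return(data.frame(label = label, dsc = NA_real_,
                        hd_fixed_to_moving = NA_real_,
                        hd_moving_to_fixed = NA_real_, hd = NA_real_,
                        status = "missing", stringsAsFactors = FALSE))
    wm <- warp_mask(pair$moving, field)
    if (sum(wm$voxels) == 0 || sum(pair$fixed$voxels) == 0)
      return(data.frame(label = label, dsc = NA_real_,
                        hd_fixed_to_moving = NA_real_,
                        hd_moving_to_fixed = NA_real_, hd = NA_real_,
                        status = "empty", stringsAsFactors = FALSE))
    h_fm <- hausdorff_directed(pair$fixed, wm)
    h_mf <- hausdorff_directed(wm, pair$fixed)
    data.frame(label = label, dsc = dsc(pair$fixed, wm),
               hd_fixed_to_moving = h_fm, hd_moving_to_fixed = h_mf,
               hd = max(h_fm, h_mf), status = "ok", stringsAsFactors = FALSE)
  }
  mrow <- function(label, pair) {
    if (is.null(pair$fixed) || is.null(pair$moving) ||
        sum(pair$fixed$voxels) == 0 || sum(pair$moving$voxels) == 0)
      return(data.frame(label = label, tre_pre_mm = NA_real_,
                        tre_post_mm = NA_real_, status = "missing",
                        stringsAsFactors = FALSE))
    pre <- sqrt(sum((marker_centroid(pair$moving) -
                     marker_centroid(pair$fixed))^2))
    data.frame(label = label, tre_pre_mm = pre,
               tre_post_mm = tre(pair$moving, pair$fixed, field),
               status = "ok", stringsAsFactors = FALSE)
  }
  structures <- do.call(rbind, c(
    lapply(names(structure_pairs),
           function(nm) srow(nm, structure_pairs[[nm]])),
    list(make.row.names = FALSE)))
  markers <- do.call(rbind, c(
    lapply(names(marker_pairs), function(nm) mrow(nm, marker_pairs[[nm]])),
    list(make.row.names = FALSE)))
  structure(list(metrics = metrics, structures = structures,
                 markers = markers,
                 min_jacobian = min(jacobian_determinant(field)$voxels)),
            class = "registration_report")
}

#' @export
print.registration_report <- function(x, ...) {
  cat(sprintf("<registration_report> MI %.4f NCC %.4f MAD %.4g, min Jac %.3f\n",
              x$metrics$mi, x$metrics$ncc, x$metrics$mean_abs_diff,
              x$min_jacobian))
  if (!is.null(x$structures) && nrow(x$structures)) {
    cat("structures:\n"); print(x$structures, row.names = FALSE)
  }
  if (!is.null(x$markers) && nrow(x$markers)) {
    cat("markers:\n"); print(x$markers, row.names = FALSE)
  }
  invisible(x)
}

#' Mean endpoint error between two displacement fields (mm)
#'
#' Mean over the region (all voxels, or a mask) of the Euclidean norm of
#' the per-voxel difference; the standard scoring of a recovered field
#' against a synthetic ground truth.
#'
#' @param estimated,truth [displacement_field()]s on the same grid.
#' @param mask optional [binary_mask()] region (e.g. the phantom body).
#' @return Mean endpoint error in mm.
#' @export
endpoint_error <- function(estimated, truth, mask = NULL) {
  if (!same_grid(estimated, truth)) stop_grid_mismatch("endpoint_error", estimated, truth)
  dv <- estimated$vectors - truth$vectors
  e <- sqrt(dv[, , , 1]^2 + dv[, , , 2]^2 + dv[, , , 3]^2)
  if (!is.null(mask)) {
    keep <- mask$voxels != 0L
    if (!any(keep)) stop("endpoint_error: empty mask")
    e <- e[keep]
  }
  mean(e)
}
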