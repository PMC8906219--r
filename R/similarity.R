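#' Joint intensity histogram of two images on a shared grid
#'
#' Hard-binned counts over the whole grid (or a mask), with equal-width
#' bins spanning each image's own `[min, max]` range.  A constant image is
#' handled by widening its range by one intensity unit so the single
#' occupied bin stays well defined.
#'
#' @param fixed,moving_warped [image3d()]s on the same grid.
#' @param bins number of bins per axis (>= 2).
#' @param mask optional [binary_mask()] restricting the sample region.
#' @return A list of class `joint_histogram` with `counts` (bins x bins,
#'   fixed along rows), `edges_fixed`, `edges_moving`, `n`.
#' @export
joint_histogram <- function(fixed, moving_warped, bins = 64, mask = NULL) {
  if (!same_grid(fixed, moving_warped))
    stop_grid_mismatch("joint_histogram", fixed, moving_warped)
  if (bins < 2) stop("joint_histogram: bins must be >= 2")
  f <- as.vector(fixed$voxels); m <- as.vector(moving_warped$voxels)
  if (!is.null(mask)) {
    if (!same_grid(fixed, mask)) stop_grid_mismatch("joint_histogram", fixed, mask)
    keep <- as.vector(mask$voxels) != 0L
    if (!any(keep)) stop("joint_histogram: empty mask")
    f <- f[keep]; m <- m[keep]
  }
  rf <- range(f); rm_ <- range(m)
  if (diff(rf) == 0) rf[2] <- rf[1] + 1
  if (diff(rm_) == 0) rm_[2] <- rm_[1] + 1
  counts <- bin_counts(f, m, bins, rf, rm_)
  structure(list(counts = counts,
                 edges_fixed = seq(rf[1], rf[2], length.out = bins + 1),
                 edges_moving = seq(rm_[1], rm_[2], length.out = bins + 1),
                 n = length(f)),
            class = "joint_histogram")
}

# hard binning with fixed ranges (values clamped into range)
bin_index <- function(x, bins, r) {
  i <- floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L
  pmin.int(bins, pmax.int(1L, i))
}

bin_counts <- function(f, m, bins, rf, rm_) {
  fi <- bin_index(f, bins, rf)
  mi <- bin_index(m, bins, rm_)
  matrix(tabulate(fi + bins * (mi - 1L), nbins = bins * bins), nrow = bins)
}

#' Mutual information of a joint histogram (nats)
#'
#' `MI = sum p(f,m) log(p(f,m) / (p(f) p(m)))` over non-empty cells, using
#' the natural logarithm.  Non-negative up to floating point.
#'
#' @param h a [joint_histogram()].
#' @return MI in nats.
#' @export
mutual_information <- function(h) {
  stopifnot(inherits(h, "joint_histogram"), h$n > 0)
  mi_from_counts(h$counts)
}

mi_from_counts <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  pf <- rowSums(p); pm <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  pv <- p[nz]
  sum(pv * log(pv / (pf[nz[, 1]] * pm[nz[, 2]])))
}

entropy_from_counts <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized cross-correlation (Pearson) of two images
#'
#' @param fixed,moving_warped [image3d()]s on the same grid.
#' @param mask optional [binary_mask()] evaluation region.
#' @return Correlation in `[-1, 1]`.  Zero variance in either image is an
#'   error, not a silent 0.
#' @export
ncc <- function(fixed, moving_warped, mask = NULL) {
  if (!same_grid(fixed, moving_warped))
    stop_grid_mismatch("ncc", fixed, moving_warped)
  f <- as.vector(fixed$voxels); m <- as.vector(moving_warped$voxels)
  if (!is.null(mask)) {
    keep <- as.vector(mask$voxels) != 0L
    if (!any(keep)) stop("ncc: empty mask")
    f <- f[keep]; m <- m[keep]
  }
  vf <- stats::var(f); vm <- stats::var(m)
  if (!is.finite(vf) || !is.finite(vm) || vf <= 0 || vm <= 0)
    stop("ncc: zero intensity variance in the evaluation region")
  as.numeric(stats::cor(f, m))
}

#' Mean absolute intensity difference
#'
#' The paper-style "absolute image value difference": the mean over the
#' region of `|fixed - moving_warped|`, in intensity units.
#'
#' @inheritParams ncc
#' @return Non-negative scalar.
#' @export
mean_abs_diff <- function(fixed, moving_warped, mask = NULL) {
  if (!same_grid(fixed, moving_warped))
    stop_grid_mismatch("mean_abs_diff", fixed, moving_warped)
  d <- abs(as.vector(fixed$voxels) - as.vector(moving_warped$voxels))
  if (!is.null(mask)) {
    keep <- as.vector(mask$voxels) != 0L
    if (!any(keep)) stop("mean_abs_diff: empty mask")
    d <- d[keep]
  }
  mean(d)
}

# ---- MI force field ------------------------------------------------------

# Percentile-clamped ranges used to freeze bin edges during a registration
# stage (stabilizes the histogram against CBCT outlier intensities).
intensity_window <- function(img, probs = c(0.005, 0.995)) {
  r <- as.numeric(quantile(img$voxels, probs = probs, names = FALSE))
  if (diff(r) <= 0) r[2] <- r[1] + 1
  r
}

# Parzen-smoothed joint density for the optimization path.  Samples enter
# the histogram with partial-volume (tent-kernel) weights, so the counts
# -- and hence MI -- are piecewise-linear in the intensities; the optional
# extra Gaussian smoothing (in bins) stabilizes sparse histograms.  This
# makes the MI objective effectively C^1, with an analytic gradient that
# matches it exactly (mi_force below).
pv_smoothed_counts <- function(f, m, bins, rf, rm_, parzen_sigma_bins) {
  counts <- cpp_hist2_pv(f, m, bins, rf, rm_)
  if (parzen_sigma_bins > 0)
    counts <- matrix(cpp_gauss3(as.numeric(counts), c(bins, bins, 1L),
                                c(parzen_sigma_bins, parzen_sigma_bins, 0)),
                     nrow = bins)
  counts
}

# MI of the hard-binned, Parzen-smoothed density: the accept/reject
# objective of both optimizers.  Hard binning matters here: partial-volume
# binning rewards deformations that move sampled intensities toward bin
# centres (the classic interpolation artifact), which lets a perfectly
# registered pair drift; with hard counts such deformations only increase
# the conditional entropy and are rejected.  The *gradient* (mi_force)
# still comes from the PV-binned density, whose intensity derivative is
# exact -- the two agree on genuine alignment improvements.
smoothed_mi <- function(f, m, bins, rf, rm_, parzen_sigma_bins = 1) {
  one <- function(rf1, rm1) {
    counts <- bin_counts_clamped(f, m, bins, rf1, rm1)
    if (parzen_sigma_bins > 0)
      counts <- matrix(cpp_gauss3(as.numeric(counts), c(bins, bins, 1L),
                                  c(parzen_sigma_bins, parzen_sigma_bins, 0)),
                       nrow = bins)
    mi_from_counts(counts)
  }
  # average over two bin gratings half a bin apart: a gain that only
  # aligns samples to one grating cancels against the other, a genuine
  # alignment gain survives both
  half_f <- 0.5 * (rf[2] - rf[1]) / bins
  half_m <- 0.5 * (rm_[2] - rm_[1]) / bins
  0.5 * (one(rf, rm_) + one(rf + half_f, rm_ + half_m))
}

bin_counts_clamped <- function(f, m, bins, rf, rm_) {
  bin_counts(pmin(pmax(f, rf[1]), rf[2]), pmin(pmax(m, rm_[1]), rm_[2]),
             bins, rf, rm_)
}

# MI of the PV-binned, Parzen-smoothed density: the second vote of the
# optimizers' conjunctive acceptance rule.  The hard-binned estimator
# (smoothed_mi) can be inflated by deformations that overfit one bin
# grating / noise realization; the PV estimator by deformations that pull
# samples toward bin centres.  A trial step is kept only when BOTH
# estimators improve -- genuine alignment improves both, each artifact
# family only its own.
smoothed_mi_pv <- function(f, m, bins, rf, rm_, parzen_sigma_bins = 1) {
  mi_from_counts(pv_smoothed_counts(f, m, bins, rf, rm_, parzen_sigma_bins))
}

# Derivative lookup table for the Parzen MI (tent kernel along the fixed
# axis, cubic B-spline along the moving axis): the gradient contribution
# of sample k is
#   dMI/dm_k = (1/(n bw)) * sum_f wf(f_k) sum_o B'_o(t_k) L(f, j_k-1+o)
# with L = G_sigma * log(p / p_m) (the p_f term cancels in the gradient;
# the Gaussian transfers from the density onto the log-ratio by symmetry
# of the bilinear form).  B' is the cubic B-spline derivative, which is
# smooth and vanishes at the kernel peak, so an already-registered sample
# feels no spurious force.
pv_mi_lut <- function(f, m, bins, rf, rm_, parzen_sigma_bins) {
  sm <- pv_smoothed_counts(f, m, bins, rf, rm_, parzen_sigma_bins)
  n <- sum(sm)
  p <- sm / n
  pm <- colSums(p)
  eps <- 1e-12
  L <- log(pmax(p, eps)) - matrix(log(pmax(pm, eps)), bins, bins, byrow = TRUE)
  if (parzen_sigma_bins > 0)
    L <- matrix(cpp_gauss3(as.numeric(L), c(bins, bins, 1L),
                           c(parzen_sigma_bins, parzen_sigma_bins, 0)),
                nrow = bins)
  list(L = L, n = n)
}

# per-sample fractional tent coordinates (0-based i0 plus weight t)
pv_coords <- function(x, bins, r) {
  cc <- (pmin(pmax(x, r[1]), r[2]) - r[1]) / ((r[2] - r[1]) / bins) - 0.5
  i0 <- pmin.int(bins - 2L, pmax.int(0L, floor(cc)))
  list(i0 = as.integer(i0), t = pmin(pmax(cc - i0, 0), 1))
}

# per-sample cubic B-spline coordinates along the moving axis: 0-based
# base cell j-1 and the four derivative weights B'_0..B'_3 (per bin unit)
bspline_dcoords <- function(x, bins, r) {
  cc <- (pmin(pmax(x, r[1]), r[2]) - r[1]) / ((r[2] - r[1]) / bins) - 0.5
  j <- floor(cc)
  t <- cc - j
  t2 <- t * t
  list(j = as.integer(j),
       dw = cbind(-(1 - t)^2 / 2, (3 * t2 - 4 * t) / 2,
                  (-3 * t2 + 2 * t + 1) / 2, t2 / 2))
}

# spatial gradient (mm^-1) of an image, central differences
image_gradient <- function(img) {
  g <- array(0, dim = c(grid_dim(img), 3L))
  for (ax in 1:3) g[, , , ax] <- diff_axis(img$voxels, ax, img$spacing[ax])
  g
}

#' Mutual-information force field
#'
#' The per-voxel driving force of the fluid stage:
#' `F(x) = L'(f(x), m(x)) * grad m(x)`, where `L'` is the derivative of the
#' Parzen-smoothed pointwise MI contribution
#' `log p(f,m) - log p_f(f) - log p_m(m)` with respect to the moving
#' intensity, and `grad m` is the spatial gradient (mm^-1) of the warped
#' moving image.  The force points in the direction of locally increasing
#' MI; it vanishes wherever the moving gradient vanishes.
#'
#' @param fixed,moving_warped [image3d()]s on the same grid.
#' @param bins histogram bins (>= 8).
#' @param parzen_sigma_bins Gaussian smoothing of the joint histogram, in
#'   bins.
#' @param range_fixed,range_moving optional frozen intensity ranges for the
#'   bin edges (used by the optimizers so edges do not drift between
#'   iterations); default the percentile window of each image.
#' @param mode `"mi"` (default) or `"ssd"`, the sum-of-squared-difference
#'   force `(f - m) * grad m` for mono-modal sanity tests.
#' @return A [displacement_field()]-shaped object of class `forcefield`
#'   (arbitrary force units).
#' @export
mi_force <- function(fixed, moving_warped, bins = 64, parzen_sigma_bins = 1,
                     range_fixed = NULL, range_moving = NULL,
                     mode = c("mi", "ssd")) {
  mode <- match.arg(mode)
  if (!same_grid(fixed, moving_warped))
    stop_grid_mismatch("mi_force", fixed, moving_warped)
  d <- grid_dim(fixed)
  gm <- image_gradient(moving_warped)
  if (mode == "ssd") {
    scal <- as.vector(fixed$voxels - moving_warped$voxels)
  } else {
    if (bins < 8) stop("mi_force: bins must be >= 8")
    if (is.null(range_fixed)) range_fixed <- intensity_window(fixed)
    if (is.null(range_moving)) range_moving <- intensity_window(moving_warped)
    f <- as.vector(fixed$voxels); m <- as.vector(moving_warped$voxels)
    lut <- pv_mi_lut(f, m, bins, range_fixed, range_moving, parzen_sigma_bins)
    cf <- pv_coords(f, bins, range_fixed)
    cm <- bspline_dcoords(m, bins, range_moving)
    bw_m <- (range_moving[2] - range_moving[1]) / bins
    L <- lut$L
    scal <- 0
    for (o in 0:3) {
      jj <- pmin.int(bins - 1L, pmax.int(0L, cm$j - 1L + o)) + 1L
      Ldiff <- (1 - cf$t) * L[cbind(cf$i0 + 1L, jj)] +
        cf$t * L[cbind(cf$i0 + 2L, jj)]
      scal <- scal + cm$dw[, o + 1] * Ldiff
    }
    scal <- scal / (bw_m * lut$n)
    # a moving intensity clamped by the window does not move in bin space,
    # so its true derivative is zero
    scal[m <= range_moving[1] | m >= range_moving[2]] <- 0
  }
  out <- array(0, dim = c(d, 3L))
  for (c in 1:3) out[, , , c] <- array(scal, dim = d) * gm[, , , c]
  structure(list(vectors = out, spacing = fixed$spacing, origin = fixed$origin),
            class = c("forcefield", "dispfield"))
}

# Convenience: hard-binned MI metric of two images (reporting path).
mi_metric <- function(fixed, moving_warped, bins = 64, mask = NULL) {
  mutual_information(joint_histogram(fixed, moving_warped, bins, mask))
}
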