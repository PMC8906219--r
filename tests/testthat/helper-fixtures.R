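# Shared fixtures.  Everything is generated in code; the heavier phantom
# objects are cached per test run so multiple test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# linear ramp image: intensity a + b*i along one axis (0-based index)
ramp_image <- function(d = c(8, 8, 8), axis = 1, a = 0, b = 1,
                       spacing = c(1, 1, 1)) {
  idx <- switch(axis,
                array(rep(0:(d[1] - 1), times = d[2] * d[3]), dim = d),
                array(rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]), dim = d),
                array(rep(0:(d[3] - 1), each = d[1] * d[2]), dim = d))
  image3d(a + b * idx, spacing = spacing)
}

cube_mask <- function(d = c(12, 12, 12), from = c(4, 4, 4), to = c(7, 7, 7),
                      spacing = c(1, 1, 1)) {
  v <- array(0L, dim = d)
  v[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- 1L
  binary_mask(v, spacing = spacing)
}

constant_field <- function(img, u = c(0, 0, 0)) {
  f <- zero_field(img)
  for (c in 1:3) f$vectors[, , , c] <- u[c]
  f
}

# small phantom shared across similarity / ffd / fluid tests
small_phantom <- function() cached("small_phantom",
  make_phantom(phantom_spec(shape = c(32, 32, 32), seed = 11)))

small_case_clean <- function() cached("small_case_clean",
  make_case(phantom_spec(shape = c(32, 32, 32), seed = 12),
            cp_spacing_mm = 32, max_disp_mm = 6, degrade = NULL, seed = 12))

small_case_degraded <- function() cached("small_case_degraded",
  make_case(phantom_spec(shape = c(32, 32, 32), seed = 13),
            cp_spacing_mm = 32, max_disp_mm = 6, seed = 13))

# brute-force oracles (kept deliberately naive and independent)

oracle_hausdorff_directed <- function(a, b, surface = TRUE) {
  pts <- function(mask) {
    w <- which(mask$voxels == 1L, arr.ind = TRUE)
    if (surface) {
      keep <- logical(nrow(w))
      d <- dim(mask$voxels)
      for (r in seq_len(nrow(w))) {
        i <- w[r, 1]; j <- w[r, 2]; k <- w[r, 3]
        nb6 <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                     c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
        out <- apply(nb6, 1, function(p)
          any(p < 1) || any(p > d) || mask$voxels[p[1], p[2], p[3]] == 0L)
        keep[r] <- any(out)
      }
      w <- w[keep, , drop = FALSE]
    }
    sweep(sweep(w - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
  }
  A <- pts(a); B <- pts(b)
  mx <- 0
  for (r in seq_len(nrow(A))) {
    dmin <- min(sqrt(colSums((t(B) - A[r, ])^2)))
    if (dmin > mx) mx <- dmin
  }
  mx
}

oracle_mi <- function(af, am, bins) {
  f <- as.vector(af); m <- as.vector(am)
  rf <- range(f); rm_ <- range(m)
  if (diff(rf) == 0) rf[2] <- rf[1] + 1
  if (diff(rm_) == 0) rm_[2] <- rm_[1] + 1
  cutf <- function(x, r) pmin(bins, pmax(1, floor((x - r[1]) / (r[2] - r[1]) * bins) + 1))
  tab <- matrix(0, bins, bins)
  fi <- cutf(f, rf); mi <- cutf(m, rm_)
  for (k in seq_along(f)) tab[fi[k], mi[k]] <- tab[fi[k], mi[k]] + 1
  p <- tab / sum(tab)
  s <- 0
  for (i in 1:bins) for (j in 1:bins) if (p[i, j] > 0)
    s <- s + p[i, j] * log(p[i, j] / (sum(p[i, ]) * sum(p[, j])))
  s
}
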