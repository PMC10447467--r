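# Small separable filtering helpers shared by the phantom generator and the
# augmentation transforms. Edges are handled by renormalizing the kernel mass
# that falls inside the support (equivalent to zero padding + weight
# renormalization), so constant inputs stay constant up to the boundary.

# convolve each column of a matrix with a 1-D kernel (odd length), normalized
# at the edges
conv_cols_norm <- function(mat, kernel) {
  k <- length(kernel)
  stopifnot(k %% 2L == 1L)
  half <- (k - 1L) %/% 2L
  n <- nrow(mat)
  acc <- matrix(0, n, ncol(mat))
  wgt <- numeric(n)
  for (j in seq_len(k)) {
    off <- j - 1L - half
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    acc[ok, ] <- acc[ok, ] + kernel[j] * mat[src[ok], , drop = FALSE]
    wgt[ok] <- wgt[ok] + kernel[j]
  }
  acc / wgt
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# smooth Gaussian random field: white noise filtered at per-axis sigma
# (voxels). For large sigmas the field is generated on a decimated lattice and
# linearly upsampled, which preserves the correlation structure at a fraction
# of the cost.
smooth_noise_field <- function(d, sigma) {
  dec <- pmax(1L, pmin(floor(sigma / 1.5), 4L))
  dd <- pmax(4L, as.integer(ceiling(d / dec)))
  f <- gaussian_filter_3d(array(stats::rnorm(prod(dd)), dd), sigma / dec)
  if (all(dd == d)) return(f)
  for (ax in 1:3) {
    if (dd[ax] == d[ax]) next
    pos <- seq(1, dim(f)[ax], length.out = d[ax])
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(f, perm)
    da <- dim(a)
    m <- interp_cols_linear(matrix(a, nrow = da[1]), pos)
    f <- aperm(array(m, c(d[ax], da[2], da[3])), order(perm))
  }
  f
}

# separable Gaussian filter along every axis of a 3-D array; sigma is per-axis
# (in voxels); sigma of 0 skips the axis
gaussian_filter_3d <- function(arr, sigma) {
  d <- dim(arr)
  stopifnot(length(d) == 3L, length(sigma) == 3L)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    kern <- gaussian_kernel_1d(sigma[ax])
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    dd <- dim(a)
    m <- conv_cols_norm(matrix(a, nrow = dd[1]), kern)
    a <- array(m, dd)
    arr <- aperm(a, order(perm))
  }
  arr
}

# separable Gaussian blur of a 2-D matrix
gaussian_blur_2d <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  kern <- gaussian_kernel_1d(sigma)
  t(conv_cols_norm(t(conv_cols_norm(mat, kern)), kern))
}

# 3x3 discrete Laplacian with zero padding outside the support
laplacian_2d <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  up <- rbind(mat[-1, , drop = FALSE], 0)
  dn <- rbind(0, mat[-n, , drop = FALSE])
  lf <- cbind(mat[, -1, drop = FALSE], 0)
  rt <- cbind(0, mat[, -m, drop = FALSE])
  up + dn + lf + rt - 4 * mat
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# linear 1-D interpolation of each column of `mat` at fractional row
# positions `pos` (1-based, clamped to the support)
interp_cols_linear <- function(mat, pos) {
  n <- nrow(mat)
  pos <- pmin(pmax(pos, 1), n)
  i0 <- pmin(floor(pos), n - ifelse(n > 1, 1, 0))
  i0 <- pmax(i0, 1)
  w <- pos - i0
  i1 <- pmin(i0 + 1, n)
  (1 - w) * mat[i0, , drop = FALSE] + w * mat[i1, , drop = FALSE]
}
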