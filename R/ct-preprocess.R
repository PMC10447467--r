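# CT preprocessing: trilinear resampling to a common voxel grid, HU windowing,
# tumor-centered 5-slice selection, and training-time augmentation.
#
# Conventions: volumes are arrays indexed (z, y, x); spacing is the mm triple
# (z, y, x); masks are strictly binary (0/1) after any resampling.

#' Construct an image volume
#'
#' @param voxels 3-D numeric array in (z, y, x) order; HU values for CT.
#' @param spacing Positive mm triple (z, y, x).
#' @param origin mm triple, default zeros.
#' @return An `image_volume` object.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(voxels)) == 3L, length(spacing) == 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be positive on all axes")
  if (any(!is.finite(voxels))) stop("voxels must be finite")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' Read / write an image volume as NIfTI
#'
#' The NIfTI affine carries the voxel spacing. On disk the array follows the
#' NIfTI (x, y, z) convention; in memory this package uses (z, y, x).
#'
#' @param path `.nii` or `.nii.gz` file path.
#' @param volume An `image_volume`.
#' @return An `image_volume` (read) or `path` invisibly (write).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- aperm(as.array(img), c(3, 2, 1))
  spc <- rev(RNifti::pixdim(img))
  image_volume(vox, spc)
}

#' @rdname read_volume_nifti
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  arr <- aperm(volume$voxels, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(volume$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume to a target spacing
#'
#' Separable trilinear interpolation onto a grid whose extent covers the input
#' physical extent; sample positions beyond the last input voxel center clamp
#' to the edge. Masks use `method = "nearest"` and are re-binarized at 0.5.
#'
#' @param volume An `image_volume`.
#' @param target_spacing mm triple (z, y, x); default `c(2.5, 0.75, 0.75)`.
#' @param method `"trilinear"` (default) or `"nearest"`.
#' @return A resampled `image_volume`.
#' @export
resample_volume <- function(volume, target_spacing = c(2.5, 0.75, 0.75),
                            method = c("trilinear", "nearest")) {
  stopifnot(inherits(volume, "image_volume"))
  method <- match.arg(method)
  if (any(target_spacing <= 0)) stop("target_spacing must be positive")
  arr <- volume$voxels
  for (ax in 1:3) {
    s_in <- volume$spacing[ax]
    s_out <- target_spacing[ax]
    n_in <- dim(arr)[ax]
    n_out <- max(1L, as.integer(ceiling(n_in * s_in / s_out)))
    pos <- 1 + (seq_len(n_out) - 1) * s_out / s_in   # fractional input index
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    dd <- dim(a)
    m <- matrix(a, nrow = dd[1])
    m2 <- if (method == "trilinear") {
      interp_cols_linear(m, pos)
    } else {
      m[pmin(pmax(round(pos), 1), dd[1]), , drop = FALSE]
    }
    a2 <- array(m2, c(n_out, dd[2], dd[3]))
    arr <- aperm(a2, order(perm))
  }
  if (method == "nearest") arr <- (arr > 0.5) + 0
  image_volume(arr, target_spacing, volume$origin)
}

#' Window and normalize CT intensities
#'
#' Clips HU values to the soft-tissue window and maps the window affinely to
#' `[0, 1]`.
#'
#' @param volume An `image_volume` (HU) or a numeric array.
#' @param window HU window, default `c(-150, 150)`.
#' @return Same type as input with values in `[0, 1]`.
#' @export
window_normalize <- function(volume, window = c(-150, 150)) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  f <- function(x) (pmin(pmax(x, window[1]), window[2]) - window[1]) /
    (window[2] - window[1])
  if (inherits(volume, "image_volume")) {
    volume$voxels <- f(volume$voxels)
    volume
  } else f(volume)
}

#' Select the tumor-centered 5-slice stack
#'
#' The anchor is the axial slice with the largest in-plane tumor-mask area;
#' `k` consecutive slices centered on it are taken (edge slices are repeated
#' when the volume ends), and each is cropped to `crop x crop` pixels centered
#' on the anchor-slice mask centroid. Out-of-volume pixels are padded with 0
#' (the normalized background floor).
#'
#' @param volume A windowed/normalized `image_volume`.
#' @param mask Binary `image_volume` (same grid) marking the tumor.
#' @param k Number of slices (default 5).
#' @param crop In-plane crop size in voxels (default 160).
#' @return A `slice_stack`: list with `planes` (k x crop x crop array),
#'   `source_slice_indices`, `crop_center` (y, x voxel coords of the centroid).
#' @export
select_slices <- function(volume, mask, k = 5L, crop = 160L) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "image_volume"))
  if (!all(dim(volume$voxels) == dim(mask$voxels)))
    stop("volume and mask grids differ")
  m <- mask$voxels
  if (sum(m) == 0) stop("tumor not identified: mask is empty")
  areas <- apply(m, 1, sum)
  anchor <- which.max(areas)
  nz <- dim(m)[1]
  idx <- pmin(pmax(anchor + seq_len(k) - 1L - (k %/% 2L), 1L), nz)

  sl <- m[anchor, , ]
  ys <- row(sl)[sl > 0]; xs <- col(sl)[sl > 0]
  cy <- mean(ys); cx <- mean(xs)
  cy0 <- round(cy); cx0 <- round(cx)
  half <- crop %/% 2L
  rows <- (cy0 - half + 1L):(cy0 + crop - half)
  cols <- (cx0 - half + 1L):(cx0 + crop - half)

  ny <- dim(m)[2]; nx <- dim(m)[3]
  planes <- array(0, c(k, crop, crop))
  rok <- rows >= 1L & rows <= ny
  cok <- cols >= 1L & cols <= nx
  for (i in seq_len(k)) {
    planes[i, which(rok), which(cok)] <-
      volume$voxels[idx[i], rows[rok], cols[cok]]
  }
  structure(list(planes = planes,
                 source_slice_indices = as.integer(idx),
                 crop_center = c(y = cy, x = cx)),
            class = "slice_stack")
}

#' Training augmentation policy
#'
#' Probabilities and parameter ranges for the on-the-fly augmentations:
#' anterior/posterior and left/right reflection, random translation, Gaussian
#' blur, unsharp-mask sharpening, and Laplacian enhancement. Geometric
#' transforms are shared across the 5 planes.
#'
#' @param p_flip_lr,p_flip_ap,p_translate,p_blur,p_sharpen,p_laplacian
#'   Per-transform probabilities in `[0, 1]`.
#' @param translate_max Maximum absolute translation, voxels (integer shifts).
#' @param blur_sigma Range of the Gaussian blur sigma (voxels).
#' @param sharpen_strength,laplacian_strength Strength ranges.
#' @return An `augment_policy` object.
#' @export
augment_policy <- function(p_flip_lr = 0.5, p_flip_ap = 0.5,
                           p_translate = 0.5, translate_max = 8L,
                           p_blur = 0.25, blur_sigma = c(0.5, 1.5),
                           p_sharpen = 0.25, sharpen_strength = c(0.3, 1),
                           p_laplacian = 0.25, laplacian_strength = c(0.1, 0.4)) {
  p <- c(p_flip_lr, p_flip_ap, p_translate, p_blur, p_sharpen, p_laplacian)
  if (any(p < 0 | p > 1)) stop("augmentation probabilities must be in [0, 1]")
  structure(list(p_flip_lr = p_flip_lr, p_flip_ap = p_flip_ap,
                 p_translate = p_translate, translate_max = as.integer(translate_max),
                 p_blur = p_blur, blur_sigma = blur_sigma,
                 p_sharpen = p_sharpen, sharpen_strength = sharpen_strength,
                 p_laplacian = p_laplacian, laplacian_strength = laplacian_strength),
            class = "augment_policy")
}

shift_plane <- function(mat, dy, dx) {
  out <- matrix(0, nrow(mat), ncol(mat))
  src_r <- seq_len(nrow(mat)) - dy
  src_c <- seq_len(ncol(mat)) - dx
  rok <- src_r >= 1 & src_r <= nrow(mat)
  cok <- src_c >= 1 & src_c <= ncol(mat)
  out[which(rok), which(cok)] <- mat[src_r[rok], src_c[cok]]
  out
}

#' Augment a slice stack
#'
#' Applies each transform of the policy independently with its probability,
#' using the same geometric parameters for all planes; output is re-clipped to
#' `[0, 1]`. Deterministic under a fixed RNG state.
#'
#' @param stack A `slice_stack`.
#' @param policy An `augment_policy`.
#' @return An augmented `slice_stack`.
#' @export
augment_stack <- function(stack, policy = augment_policy()) {
  stopifnot(inherits(stack, "slice_stack"), inherits(policy, "augment_policy"))
  pl <- stack$planes
  k <- dim(pl)[1]
  do_lr <- stats::runif(1) < policy$p_flip_lr
  do_ap <- stats::runif(1) < policy$p_flip_ap
  do_tr <- stats::runif(1) < policy$p_translate
  dy <- dx <- 0L
  if (do_tr) {
    dy <- sample.int(2L * policy$translate_max + 1L, 1L) - policy$translate_max - 1L
    dx <- sample.int(2L * policy$translate_max + 1L, 1L) - policy$translate_max - 1L
  }
  do_bl <- stats::runif(1) < policy$p_blur
  sig <- stats::runif(1, policy$blur_sigma[1], policy$blur_sigma[2])
  do_sh <- stats::runif(1) < policy$p_sharpen
  sh <- stats::runif(1, policy$sharpen_strength[1], policy$sharpen_strength[2])
  do_la <- stats::runif(1) < policy$p_laplacian
  la <- stats::runif(1, policy$laplacian_strength[1], policy$laplacian_strength[2])

  for (i in seq_len(k)) {
    p <- pl[i, , ]
    if (do_lr) p <- p[, rev(seq_len(ncol(p)))]       # left/right: x axis
    if (do_ap) p <- p[rev(seq_len(nrow(p))), ]       # anterior/posterior: y axis
    if (do_tr) p <- shift_plane(p, dy, dx)
    if (do_bl) p <- gaussian_blur_2d(p, sig)
    if (do_sh) p <- p + sh * (p - gaussian_blur_2d(p, 1))
    if (do_la) p <- p - la * laplacian_2d(p)
    pl[i, , ] <- clip01(p)
  }
  stack$planes <- pl
  stack
}

#' Full deterministic preprocessing of one subject
#'
#' resample (trilinear volume / nearest mask) -> HU windowing -> tumor-centered
#' slice selection. Augmentation is a separate training-time step.
#'
#' @param volume CT `image_volume` in HU.
#' @param mask Binary tumor `image_volume` on the same grid.
#' @param target_spacing,window,k,crop See the individual steps.
#' @return A `slice_stack`.
#' @export
preprocess_subject <- function(volume, mask,
                               target_spacing = c(2.5, 0.75, 0.75),
                               window = c(-150, 150), k = 5L, crop = 160L) {
  v <- resample_volume(volume, target_spacing, "trilinear")
  m <- resample_volume(mask, target_spacing, "nearest")
  v <- window_normalize(v, window)
  select_slices(v, m, k = k, crop = crop)
}
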