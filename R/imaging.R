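#' @name imaging
#' @title Grayscale image primitives
#' @description
#' Images are plain integer matrices with intensities in `[0, 255]`
#' (row = image row).  Binary masks use the two values `{0, 255}`.
#' Smoothing filters use replicate padding at the borders and round-half-up
#' rounding; binary morphology treats everything outside the image as
#' background (zero padding).
NULL

round_half_up <- function(x) floor(x + 0.5)

clamp8 <- function(x) pmin(pmax(x, 0), 255)

check_gray <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix")
  if (any(!is.finite(img)) || any(img < 0) || any(img > 255))
    stop("image intensities must be finite and within [0, 255]")
  invisible(img)
}

check_mask <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 255)))
    stop("mask must be a matrix over {0, 255}")
  invisible(mask)
}

check_odd_size <- function(size) {
  if (length(size) != 1L || size < 3L || size %% 2L != 1L)
    stop("window size must be an odd integer >= 3")
  as.integer(size)
}

# replicate-pad a matrix by r rows/cols on every side
pad_replicate <- function(img, r) {
  ri <- c(rep(1L, r), seq_len(nrow(img)), rep(nrow(img), r))
  ci <- c(rep(1L, r), seq_len(ncol(img)), rep(ncol(img), r))
  img[ri, ci, drop = FALSE]
}

# zero-pad a matrix by r rows/cols on every side
pad_zero <- function(img, r) {
  out <- matrix(0, nrow(img) + 2L * r, ncol(img) + 2L * r)
  out[r + seq_len(nrow(img)), r + seq_len(ncol(img))] <- img
  out
}

# all size^2 shifted views of the padded image, as an (npix x size^2) matrix
neighborhoods <- function(padded, h, w, size) {
  r <- (size - 1L) %/% 2L
  k2 <- size * size
  out <- matrix(0, h * w, k2)
  j <- 0L
  for (dx in -r:r) for (dy in -r:r) {
    j <- j + 1L
    out[, j] <- as.vector(padded[(r + 1L + dy):(r + h + dy),
                                 (r + 1L + dx):(r + w + dx)])
  }
  out
}

#' Mean (box) smoothing filter
#'
#' Replaces every pixel by the rounded arithmetic mean of its
#' `size` x `size` neighborhood (replicate padding at the borders,
#' round-half-up, clamped to `[0, 255]`).
#'
#' @param img grayscale image matrix, intensities in `[0, 255]`.
#' @param size odd window size >= 3.
#' @return Filtered image matrix.
#' @export
mean_filter <- function(img, size = 3L) {
  check_gray(img); size <- check_odd_size(size)
  r <- (size - 1L) %/% 2L
  nb <- neighborhoods(pad_replicate(img, r), nrow(img), ncol(img), size)
  matrix(clamp8(round_half_up(rowMeans(nb))), nrow(img), ncol(img))
}

#' Median smoothing filter
#'
#' Replaces every pixel by the median of its `size` x `size` neighborhood
#' (replicate padding).  The pipeline default is a 9 x 9 window, which
#' removes residual speckle and bone fragments while preserving edges.
#'
#' @inheritParams mean_filter
#' @return Filtered image matrix.
#' @export
median_filter <- function(img, size = 9L) {
  check_gray(img); size <- check_odd_size(size)
  r <- (size - 1L) %/% 2L
  nb <- neighborhoods(pad_replicate(img, r), nrow(img), ncol(img), size)
  med <- apply(nb, 1L, stats::median)
  matrix(clamp8(round_half_up(med)), nrow(img), ncol(img))
}

#' Skull removal by upper intensity thresholding
#'
#' Pixels strictly brighter than the threshold `alpha` (bone tissue on CT)
#' are set to 0; all other pixels keep their value, preserving the soft
#' tissue of interest.
#'
#' @param img grayscale image matrix.
#' @param alpha threshold in `[0, 255]`.
#' @return Image matrix with supra-threshold pixels zeroed.
#' @export
remove_skull <- function(img, alpha) {
  check_gray(img)
  if (length(alpha) != 1L || alpha < 0 || alpha > 255)
    stop("alpha must be a single value in [0, 255]")
  matrix(ifelse(img > alpha, 0, img), nrow(img), ncol(img))
}

#' Band segmentation of candidate hemorrhage regions
#'
#' Produces a binary mask marking (255) the pixels whose intensity lies in
#' the closed band `[alpha1, alpha2]`; all other pixels are 0.  On skull-
#' stripped CT the band is chosen to cover hyperdense blood.
#'
#' @param img grayscale image matrix.
#' @param alpha1,alpha2 band limits, `0 <= alpha1 <= alpha2 <= 255`.
#' @return Binary mask matrix over `{0, 255}`.
#' @export
segment_hemorrhage <- function(img, alpha1, alpha2) {
  check_gray(img)
  if (alpha1 > alpha2) stop("alpha1 must be <= alpha2")
  if (alpha1 < 0 || alpha2 > 255) stop("band limits must lie in [0, 255]")
  matrix(ifelse(img >= alpha1 & img <= alpha2, 255, 0),
         nrow(img), ncol(img))
}

#' Structuring element
#'
#' A small binary matrix with odd dimensions and its origin at the center
#' cell (which must be set).  The default is the full 3 x 3 square.
#'
#' @param size odd side length (default 3), or a binary matrix to validate.
#' @return Binary matrix usable by [erode()] / [dilate()].
#' @export
structuring_element <- function(size = 3L) {
  se <- if (is.matrix(size)) size else matrix(1, size, size)
  if (nrow(se) %% 2L != 1L || ncol(se) %% 2L != 1L)
    stop("structuring element dimensions must be odd")
  if (!all(se %in% c(0, 1))) stop("structuring element must be binary")
  if (se[(nrow(se) + 1L) %/% 2L, (ncol(se) + 1L) %/% 2L] != 1)
    stop("structuring element origin (center cell) must be set")
  se
}

# offsets (drow, dcol) of the set cells of a structuring element,
# relative to its center
se_offsets <- function(se) {
  idx <- which(se == 1, arr.ind = TRUE)
  cbind(idx[, 1L] - (nrow(se) + 1L) %/% 2L,
        idx[, 2L] - (ncol(se) + 1L) %/% 2L)
}

# shift foreground logical matrix by (dr, dc), filling with `fill`
shift_logical <- function(fg, dr, dc, fill = FALSE) {
  h <- nrow(fg); w <- ncol(fg)
  out <- matrix(fill, h, w)
  rs <- max(1L, 1L - dr):min(h, h - dr)
  cs <- max(1L, 1L - dc):min(w, w - dc)
  if (length(rs) > 0L && length(cs) > 0L)
    out[rs, cs] <- fg[rs + dr, cs + dc]
  out
}

#' Binary erosion
#'
#' A pixel of the output is foreground iff the structuring element,
#' translated to that pixel, fits entirely inside the mask foreground
#' (pixels outside the image count as background).
#'
#' @param mask binary mask matrix over `{0, 255}`.
#' @param se structuring element (see [structuring_element()]).
#' @return Eroded binary mask.
#' @export
erode <- function(mask, se = structuring_element()) {
  check_mask(mask); se <- structuring_element(se)
  fg <- mask == 255
  ok <- matrix(TRUE, nrow(mask), ncol(mask))
  off <- se_offsets(se)
  for (i in seq_len(nrow(off)))
    ok <- ok & shift_logical(fg, off[i, 1L], off[i, 2L], fill = FALSE)
  matrix(ifelse(ok, 255, 0), nrow(mask), ncol(mask))
}

#' Binary dilation
#'
#' A pixel of the output is foreground iff the reflected structuring
#' element, translated to that pixel, intersects the mask foreground —
#' the dual of [erode()], gradually enlarging region boundaries.
#'
#' @inheritParams erode
#' @return Dilated binary mask.
#' @export
dilate <- function(mask, se = structuring_element()) {
  check_mask(mask); se <- structuring_element(se)
  fg <- mask == 255
  any_hit <- matrix(FALSE, nrow(mask), ncol(mask))
  off <- se_offsets(se)   # reflection: A(z - b) for b in B
  for (i in seq_len(nrow(off)))
    any_hit <- any_hit | shift_logical(fg, -off[i, 1L], -off[i, 2L],
                                       fill = FALSE)
  matrix(ifelse(any_hit, 255, 0), nrow(mask), ncol(mask))
}

#' Superimpose a binary mask onto a grayscale image
#'
#' Highlights the mask foreground on the base image: where the mask is 255
#' the output is 255; elsewhere the base image is kept unchanged, so the
#' grayscale properties outside the regions of interest are preserved.
#'
#' @param base grayscale image matrix.
#' @param mask binary mask of the same shape.
#' @return Image matrix with mask regions saturated to 255.
#' @export
superimpose <- function(base, mask) {
  check_gray(base); check_mask(mask)
  if (!all(dim(base) == dim(mask)))
    stop("base image and mask must have the same shape")
  matrix(ifelse(mask == 255, 255, base), nrow(base), ncol(base))
}

#' Flatten / rebuild an image as a pattern vector
#'
#' `flatten_image()` concatenates the image row-major into a length
#' `nrow * ncol` vector (so a 128 x 128 image becomes a 16384-attribute
#' pattern); `unflatten_image()` inverts it given the original shape.
#'
#' @param img grayscale image matrix.
#' @return `flatten_image()`: numeric vector. `unflatten_image()`: matrix.
#' @export
flatten_image <- function(img) {
  check_gray(img)
  as.vector(t(img))
}

#' @rdname flatten_image
#' @param v pattern vector of length `prod(shape)`.
#' @param shape `c(rows, cols)` of the original image.
#' @export
unflatten_image <- function(v, shape) {
  if (length(v) != prod(shape)) stop("vector length does not match shape")
  matrix(v, shape[1L], shape[2L], byrow = TRUE)
}

#' Estimate an intensity threshold from a calibration set
#'
#' The generalized threshold is the average over a (reduced) set of images
#' of each image's mean intensity.  With `region` masks the per-image mean
#' is taken over the region foreground only, which is how band limits are
#' calibrated from marked regions.
#'
#' @param images list of grayscale image matrices.
#' @param regions optional list of binary masks (same shapes) restricting
#'   each per-image mean to the mask foreground.
#' @return The estimated threshold (numeric scalar).
#' @export
estimate_alpha <- function(images, regions = NULL) {
  if (length(images) == 0L) stop("empty calibration set")
  vals <- vapply(seq_along(images), function(i) {
    img <- images[[i]]
    check_gray(img)
    if (is.null(regions)) return(mean(img))
    msk <- regions[[i]]
    check_mask(msk)
    if (!any(msk == 255)) stop("empty region mask in calibration image ", i)
    mean(img[msk == 255])
  }, numeric(1L))
  mean(vals)
}
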