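#' @name synthetic
#' @title Seeded synthetic data generators
#' @description
#' Generators for (i) two-class feature tables in which a known subset of
#' attributes carries a class-mean shift, emulating microarray-style
#' inputs, and (ii) phantom head images with a bright elliptical skull
#' ring, mid-gray brain tissue, an optional brighter hemorrhage blob and
#' additive noise, emulating 8-bit CT slices.  Every generator is fully
#' deterministic given its seed and returns the ground truth (informative
#' positions, blob mask) alongside the data, so downstream stages are
#' validated by parameter/region recovery, not by resemblance to real CT.
NULL

# run `expr` under a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic two-class feature table
#'
#' Draws Gaussian attribute values with a mean shift `delta` added, for
#' the second class only, on exactly `n_informative` randomly chosen
#' attribute positions; all remaining attributes are pure noise.  These
#' informative positions are the ground truth the dMeans ranking should
#' recover when `delta` dominates `sigma`.
#'
#' @param m_per_class patterns per class: single integer or
#'   `c(m1, m2)`.
#' @param n number of attributes.
#' @param n_informative number of shifted attributes, `<= n`.
#' @param delta class-mean shift on the informative attributes
#'   (attribute units).
#' @param sigma within-class noise standard deviation, `>= 0`.
#' @param baseline common attribute mean (default 0).
#' @param labels the two class labels; the second receives the shift.
#' @param seed RNG seed.
#' @return List with `dataset` (a [feature_dataset()]) and `informative`
#'   (sorted 1-based positions of the shifted attributes).
#' @examples
#' tab <- synth_table(10, n = 20, n_informative = 3, delta = 5, seed = 1)
#' tab$informative
#' @export
synth_table <- function(m_per_class, n, n_informative, delta,
                        sigma = 1, baseline = 0,
                        labels = c("classA", "classB"), seed = 1L) {
  if (length(m_per_class) == 1L) m_per_class <- rep(m_per_class, 2L)
  stopifnot(length(m_per_class) == 2L, all(m_per_class >= 1L),
            n >= 2L, n_informative >= 0L, n_informative <= n, sigma >= 0,
            length(labels) == 2L, labels[1L] != labels[2L])
  with_seed(seed, {
    informative <- sort(sample.int(n, n_informative))
    m <- sum(m_per_class)
    x <- matrix(stats::rnorm(m * n, mean = baseline, sd = sigma), m, n)
    cls2 <- (m_per_class[1L] + 1L):m
    x[cls2, informative] <- x[cls2, informative] + delta
    lab <- rep(labels, m_per_class)
    list(dataset = feature_dataset(x, lab), informative = informative)
  })
}

#' Synthetic phantom head image
#'
#' Builds a dark background with a bright elliptical skull ring, a
#' mid-gray brain interior, and optionally a brighter elliptical
#' hemorrhage blob inside the brain; per-pixel intensities are drawn
#' uniformly from each component's band, additive Gaussian noise is added,
#' and the result is rounded and clamped to `[0, 255]`.  The component
#' bands are non-overlapping by default so each preprocessing stage has a
#' clean oracle.  The exact blob mask is returned as ground truth.
#'
#' @param size image side length in pixels (square; default 128).
#' @param skull_intensity bone-band intensity range `c(lo, hi)`.
#' @param brain_intensity soft-tissue intensity range.
#' @param blob `NULL` for no hemorrhage, or a list with `center`
#'   (row, col), `radii` (row, col semi-axes in pixels) and `intensity`
#'   range (chosen inside the segmentation band); defaults place a blob
#'   near the ventricles with intensities in `[150, 190]`.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed RNG seed.
#' @return List with `image` (grayscale matrix), `blob_mask` (binary
#'   `{0, 255}` mask of the planted blob) and `regions` (logical masks
#'   `skull`, `brain`).
#' @export
synth_phantom <- function(size = 128L,
                          skull_intensity = c(220, 255),
                          brain_intensity = c(70, 120),
                          blob = list(center = NULL, radii = NULL,
                                      intensity = c(150, 190)),
                          noise_sd = 2, seed = 1L) {
  size <- as.integer(size)
  stopifnot(size >= 16L, noise_sd >= 0)
  ctr <- (size + 1) / 2
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  ell <- function(c0, r0) ((rows - c0[1L]) / r0[1L])^2 +
                          ((cols - c0[2L]) / r0[2L])^2 <= 1
  outer_r <- c(0.45, 0.40) * size
  inner_r <- c(0.38, 0.33) * size
  skull <- ell(c(ctr, ctr), outer_r) & !ell(c(ctr, ctr), inner_r)
  brain <- ell(c(ctr, ctr), inner_r)

  blob_mask <- matrix(FALSE, size, size)
  if (!is.null(blob)) {
    if (is.null(blob$center)) blob$center <- c(ctr - 0.05 * size,
                                               ctr + 0.05 * size)
    if (is.null(blob$radii)) blob$radii <- c(0.10, 0.08) * size
    if (is.null(blob$intensity)) blob$intensity <- c(150, 190)
    blob_mask <- ell(blob$center, blob$radii)
    if (any(blob_mask & !brain))
      stop("hemorrhage blob extends outside the brain region")
  }

  with_seed(seed, {
    img <- matrix(stats::runif(size * size, 0, 10), size, size)
    img[brain] <- stats::runif(sum(brain), brain_intensity[1L],
                               brain_intensity[2L])
    img[skull] <- stats::runif(sum(skull), skull_intensity[1L],
                               skull_intensity[2L])
    if (any(blob_mask))
      img[blob_mask] <- stats::runif(sum(blob_mask), blob$intensity[1L],
                                     blob$intensity[2L])
    if (noise_sd > 0)
      img <- img + stats::rnorm(size * size, 0, noise_sd)
    img <- matrix(clamp8(round_half_up(img)), size, size)
    list(image = img,
         blob_mask = matrix(ifelse(blob_mask, 255, 0), size, size),
         regions = list(skull = skull, brain = brain))
  })
}

#' Write a directory of labeled phantom images
#'
#' Generates `n_per_class` phantoms per class and writes them as 8-bit
#' grayscale PNGs under `<root>/<class>/`, the layout [load_image_dataset()]
#' reads.  The first class receives a hemorrhage blob (with a small seeded
#' jitter of its center and radii), the second does not.  Bit-identical
#' across runs for the same seed.
#'
#' @param root output directory (created if needed).
#' @param n_per_class images per class: single integer or `c(n1, n2)`.
#' @param classes the two class (sub-directory) names; the first is the
#'   blob-bearing class.
#' @param size image side length.
#' @param noise_sd additive noise level passed to [synth_phantom()].
#' @param blob_intensity intensity band of the planted blobs.
#' @param seed RNG seed.
#' @return Character vector of the written file paths, invisibly.
#' @export
synth_image_dataset <- function(root, n_per_class,
                                classes = c("IVH", "Normal"),
                                size = 128L, noise_sd = 2,
                                blob_intensity = c(150, 190),
                                seed = 1L) {
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, 2L)
  stopifnot(length(n_per_class) == 2L, all(n_per_class >= 1L),
            length(classes) == 2L)
  paths <- character(0)
  with_seed(seed, {
    for (ci in 1:2) {
      dir.create(file.path(root, classes[ci]), recursive = TRUE,
                 showWarnings = FALSE)
      for (i in seq_len(n_per_class[ci])) {
        sub_seed <- sample.int(.Machine$integer.max, 1L)
        blob <- if (ci == 1L) {
          ctr <- (size + 1) / 2
          jit <- stats::runif(2, -0.06, 0.06) * size
          list(center = c(ctr, ctr) + jit,
               radii = stats::runif(2, 0.07, 0.11) * size,
               intensity = blob_intensity)
        } else NULL
        ph <- synth_phantom(size = size, blob = blob,
                            noise_sd = noise_sd, seed = sub_seed)
        p <- file.path(root, classes[ci], sprintf("phantom_%03d.png", i))
        write_gray_image(ph$image, p)
        paths <- c(paths, p)
      }
    }
  })
  invisible(paths)
}
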