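#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-wise histogram equalization with a clip limit: the image is divided
#' into a grid of tiles ("mosaics"), each tile's histogram is clipped at
#' the limit and the excess redistributed, and neighboring tile mappings
#' are blended by bilinear interpolation to avoid block boundaries.  The
#' equalization itself is performed by \code{EBImage::clahe}; this wrapper
#' handles the 8-bit scaling and replicate-pads images whose dimensions are
#' not multiples of the tile grid (cropping back afterwards).  An image
#' with zero dynamic range is returned unchanged — there is no contrast to
#' create.
#'
#' @param img grayscale image matrix, intensities in `[0, 255]`.
#' @param tiles tile grid as `c(rows, cols)` (default `c(8, 8)`).
#' @param clip contrast clip limit (default 2); higher values allow more
#'   amplification.
#' @param distribution target histogram shape; only `"uniform"` is
#'   supported.
#' @return Enhanced image matrix in `[0, 255]`.
#' @export
clahe_enhance <- function(img, tiles = c(8L, 8L), clip = 2,
                          distribution = "uniform") {
  check_gray(img)
  tiles <- as.integer(tiles)
  if (length(tiles) != 2L || any(tiles < 1L))
    stop("tiles must be two positive integers c(rows, cols)")
  if (any(tiles > dim(img)))
    stop("tile grid larger than image")
  if (!identical(distribution, "uniform"))
    stop("only the uniform redistribution is supported")
  rng <- range(img)
  if (rng[1L] == rng[2L]) return(img)

  # pad to the next multiple of the tile grid (EBImage requirement)
  h <- nrow(img); w <- ncol(img)
  hp <- ceiling(h / tiles[1L]) * tiles[1L]
  wp <- ceiling(w / tiles[2L]) * tiles[2L]
  padded <- img[c(seq_len(h), rep(h, hp - h)),
                c(seq_len(w), rep(w, wp - w)), drop = FALSE]

  # EBImage stores images column-major as (x, y): transpose in and out
  eq <- EBImage::clahe(t(padded) / 255, nx = tiles[2L], ny = tiles[1L],
                       limit = clip)
  out <- t(eq)[seq_len(h), seq_len(w), drop = FALSE]
  matrix(clamp8(round_half_up(out * 255)), h, w)
}

#' Preprocessing configuration
#'
#' Collects the tunable parameters of the enhancement/segmentation chain.
#' Thresholds are implementation defaults, not universal constants: on real
#' data `alpha` (skull threshold) and `alpha1`/`alpha2` (hemorrhage band)
#' should be calibrated, e.g. with [estimate_alpha()].
#'
#' @param clahe list with `tiles`, `clip`, `distribution` (see
#'   [clahe_enhance()]), or `NULL` to skip contrast enhancement.
#' @param noise_filter list with `kind` (`"median"` or `"mean"`) and odd
#'   `size`, or `NULL` to skip smoothing.  Default: 9 x 9 median.
#' @param alpha skull-removal threshold in `[0, 255]`.
#' @param alpha1,alpha2 hemorrhage band limits, `alpha1 <= alpha2`.
#' @param se_size structuring-element side length for morphology.
#' @param morphology order of morphological cleanup applied to the band
#'   mask: character vector over `"erode"`/`"dilate"` (default opening,
#'   `c("erode", "dilate")`), or `NULL`/empty for none.
#' @return Validated list of class `preprocess_config`.
#' @export
preprocess_config <- function(clahe = list(tiles = c(8L, 8L), clip = 2,
                                           distribution = "uniform"),
                              noise_filter = list(kind = "median",
                                                  size = 9L),
                              alpha = 200, alpha1 = 130, alpha2 = 200,
                              se_size = 3L,
                              morphology = c("erode", "dilate")) {
  if (!is.null(clahe)) {
    if (is.null(clahe$tiles)) clahe$tiles <- c(8L, 8L)
    if (is.null(clahe$clip)) clahe$clip <- 2
    if (is.null(clahe$distribution)) clahe$distribution <- "uniform"
  }
  if (!is.null(noise_filter)) {
    noise_filter$kind <- match.arg(noise_filter$kind, c("median", "mean"))
    if (is.null(noise_filter$size))
      noise_filter$size <- if (noise_filter$kind == "median") 9L else 3L
    check_odd_size(noise_filter$size)
  }
  if (alpha < 0 || alpha > 255) stop("alpha must lie in [0, 255]")
  if (alpha1 > alpha2) stop("alpha1 must be <= alpha2")
  if (alpha1 < 0 || alpha2 > 255) stop("band limits must lie in [0, 255]")
  structuring_element(as.integer(se_size))
  if (length(morphology) > 0L &&
      !all(morphology %in% c("erode", "dilate")))
    stop("morphology steps must be 'erode' or 'dilate'")
  structure(list(clahe = clahe, noise_filter = noise_filter,
                 alpha = alpha, alpha1 = alpha1, alpha2 = alpha2,
                 se_size = as.integer(se_size),
                 morphology = as.character(morphology)),
            class = "preprocess_config")
}

#' Read / write a preprocessing configuration as JSON
#'
#' @param cfg a [preprocess_config()].
#' @param path JSON file path.
#' @return `write_preprocess_config()`: `path` invisibly;
#'   `read_preprocess_config()`: a validated `preprocess_config`.
#' @export
write_preprocess_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "preprocess_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_preprocess_config
#' @export
read_preprocess_config <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(preprocess_config, o)
}

#' Full enhancement/segmentation chain
#'
#' Applies, in order: CLAHE contrast enhancement, noise smoothing
#' (median by default), skull removal by upper thresholding, band
#' segmentation of candidate hemorrhage pixels, morphological cleanup of
#' the mask, superimposition of the mask onto the skull-free image, and
#' row-major flattening into a pattern vector.  All intermediates are
#' returned for inspection and plotting.  The chain is deterministic:
#' identical image and configuration give bit-identical outputs.
#'
#' @param img grayscale image matrix in `[0, 255]`.
#' @param cfg a [preprocess_config()].
#' @return List of class `preprocess_result` with `enhanced` (the final
#'   superimposed image), `mask` (the cleaned binary mask), `pattern`
#'   (the flattened vector) and `stages`, a named list of every
#'   intermediate (`clahe`, `filtered`, `noskull`, `raw_mask`).
#' @export
preprocess_pipeline <- function(img, cfg = preprocess_config()) {
  check_gray(img)
  stopifnot(inherits(cfg, "preprocess_config"))
  eq <- if (is.null(cfg$clahe)) img else
    clahe_enhance(img, tiles = cfg$clahe$tiles, clip = cfg$clahe$clip,
                  distribution = cfg$clahe$distribution)
  filt <- if (is.null(cfg$noise_filter)) eq
          else if (cfg$noise_filter$kind == "median")
            median_filter(eq, cfg$noise_filter$size)
          else mean_filter(eq, cfg$noise_filter$size)
  noskull <- remove_skull(filt, cfg$alpha)
  raw_mask <- segment_hemorrhage(noskull, cfg$alpha1, cfg$alpha2)
  se <- structuring_element(cfg$se_size)
  mask <- raw_mask
  for (step in cfg$morphology)
    mask <- if (step == "erode") erode(mask, se) else dilate(mask, se)
  enhanced <- superimpose(noskull, mask)
  structure(list(enhanced = enhanced, mask = mask,
                 pattern = flatten_image(enhanced),
                 stages = list(clahe = eq, filtered = filt,
                               noskull = noskull, raw_mask = raw_mask)),
            class = "preprocess_result")
}
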