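#' Read a two-class feature table from delimited text
#'
#' Rows are patterns, columns are attributes plus one designated label
#' column; attribute positions are assigned 1-based in column order after
#' dropping the label column.  Any missing cell is a hard error naming the
#' offending row and column — the classifier assumes complete numeric
#' data.
#'
#' @param path CSV file path.
#' @param label name of the label column (default `"label"`).
#' @param sep field separator (default comma).
#' @return A [feature_dataset()].
#' @export
read_feature_csv <- function(path, label = "label", sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!label %in% names(df))
    stop("label column '", label, "' not found in ", path)
  feat <- df[setdiff(names(df), label)]
  for (j in seq_along(feat)) {
    v <- suppressWarnings(as.numeric(feat[[j]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0L)
      stop("missing or non-numeric value at row ", bad[1L],
           ", column '", names(feat)[j], "'")
    feat[[j]] <- v
  }
  feature_dataset(as.matrix(feat), df[[label]])
}

#' Write a feature dataset as CSV
#'
#' Inverse of [read_feature_csv()]: attribute columns `A1..An` plus a
#' label column.  Values round-trip exactly (written at full precision).
#'
#' @param ds a [feature_dataset()].
#' @param path output path.
#' @param label name for the label column.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(ds, path, label = "label") {
  stopifnot_dataset(ds)
  df <- as.data.frame(ds$x)
  names(df) <- paste0("A", seq_len(ncol(ds$x)))
  df[[label]] <- as.character(ds$labels)
  # full precision so that read -> write -> read is the identity
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read / write an 8-bit grayscale image
#'
#' PNG files are read with the \pkg{png} package; color inputs are
#' converted to grayscale with the standard Rec. 601 luminance weights
#' (0.299 R + 0.587 G + 0.114 B).  Values are scaled to integer
#' intensities in `[0, 255]`.
#'
#' @param path PNG file path.
#' @return `read_gray_image()`: an intensity matrix in `[0, 255]`;
#'   `write_gray_image()`: `path`, invisibly.
#' @export
read_gray_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3L] >= 3L)
      a <- 0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
    else a <- a[, , 1L]
  }
  matrix(clamp8(round_half_up(a * 255)), nrow(a), ncol(a))
}

#' @rdname read_gray_image
#' @param img grayscale image matrix in `[0, 255]`.
#' @export
write_gray_image <- function(img, path) {
  check_gray(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Load a class-labeled image directory as a feature dataset
#'
#' Expects exactly two class sub-directories of PNG images (layout
#' `<root>/<class>/*.png`).  Every image is run through the preprocessing
#' chain and flattened into one pattern row; files are visited in sorted
#' path order, so the resulting dataset (and any cross-validation folds
#' derived from it) is reproducible.
#'
#' @param root dataset root directory.
#' @param cfg a [preprocess_config()] applied to every image.
#' @return A [feature_dataset()] whose labels are the sub-directory
#'   names, with attributes `files` (the sorted source paths) and
#'   `image_shape`.
#' @export
load_image_dataset <- function(root, cfg = preprocess_config()) {
  dirs <- sort(list.dirs(root, recursive = FALSE))
  if (length(dirs) != 2L)
    stop("expected exactly 2 class sub-directories under ", root,
         ", found ", length(dirs))
  files <- lapply(dirs, function(d)
    sort(list.files(d, pattern = "\\.png$", ignore.case = TRUE,
                    full.names = TRUE)))
  empty <- lengths(files) == 0L
  if (any(empty))
    stop("empty class directory: ", paste(dirs[empty], collapse = ", "))
  labels <- rep(basename(dirs), lengths(files))
  files <- unlist(files)
  shape <- NULL
  rows <- lapply(files, function(f) {
    img <- read_gray_image(f)
    if (is.null(shape)) shape <<- dim(img)
    else if (!all(dim(img) == shape))
      stop("inconsistent image shape in ", f)
    preprocess_pipeline(img, cfg)$pattern
  })
  ds <- feature_dataset(do.call(rbind, rows), labels)
  attr(ds, "files") <- files
  attr(ds, "image_shape") <- shape
  ds
}
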