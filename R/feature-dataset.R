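#' Two-class feature dataset
#'
#' Bundles an m x n numeric pattern matrix with a length-m vector of class
#' labels drawn from exactly two classes.  Attribute positions are reported
#' 1-based in column order.  By convention the first class (`C1`) is the
#' class whose label sorts first (lexicographically for character labels,
#' numerically for numeric labels); this fixes the sign of the dMeans
#' differences and is recorded in every downstream result.
#'
#' @param x numeric matrix (or object coercible to one) of m patterns by n
#'   attributes; all values must be finite, with m >= 2 and n >= 2.
#' @param labels vector of length m with exactly two distinct values.
#' @return An object of class `feature_dataset`: a list with elements `x`
#'   (the matrix) and `labels` (a factor whose first level is `C1`).
#' @examples
#' ds <- feature_dataset(rbind(c(0, 10), c(0, 0)), c("a", "b"))
#' levels(ds$labels)  # "a" is C1
#' @export
feature_dataset <- function(x, labels) {
  x <- as.matrix(x)
  if (!is.numeric(x))
    stop("patterns must be numeric")
  storage.mode(x) <- "double"
  if (any(!is.finite(x)))
    stop("patterns contain missing or non-finite values")
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need at least 2 patterns and 2 attributes")
  if (length(labels) != nrow(x))
    stop("labels length (", length(labels), ") != number of patterns (",
         nrow(x), ")")
  lev <- sort(unique(labels))
  if (length(lev) != 2L)
    stop("exactly two distinct class labels required, found ", length(lev))
  labels <- factor(as.character(labels), levels = as.character(lev))
  structure(list(x = x, labels = labels), class = "feature_dataset")
}

is_feature_dataset <- function(ds) inherits(ds, "feature_dataset")

stopifnot_dataset <- function(ds) {
  if (!is_feature_dataset(ds))
    stop("not a feature_dataset")
  invisible(ds)
}

#' @export
print.feature_dataset <- function(x, ...) {
  cnt <- table(x$labels)
  cat("feature_dataset: ", nrow(x$x), " patterns x ", ncol(x$x),
      " attributes\n", sep = "")
  cat("classes: ", paste0(names(cnt), " (", as.integer(cnt), ")",
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_dataset <- function(x) dim(x$x)

# Row subset that preserves the class coding; used by the LOOCV harness.
# Errors if the subset would lose a class (every fold must retain both).
dataset_subset <- function(ds, idx, require_both = TRUE) {
  stopifnot_dataset(ds)
  x <- ds$x[idx, , drop = FALSE]
  labels <- ds$labels[idx]
  if (require_both && any(table(labels) == 0L))
    stop("subset empties a class")
  structure(list(x = x, labels = labels), class = "feature_dataset")
}

# indices of each class, in C1/C2 order
class_indices <- function(ds) {
  lapply(levels(ds$labels), function(l) which(ds$labels == l))
}
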