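#' Per-class attribute means
#'
#' Computes, for every attribute, the arithmetic mean of its values over the
#' patterns of each class: the first step of the dMeans relevance ranking.
#'
#' @param ds a [feature_dataset()].
#' @return A list with `M1` and `M2`, length-n numeric vectors of the
#'   attribute means of class `C1` and `C2` respectively, and `classes`,
#'   the two class labels in (C1, C2) order.
#' @examples
#' ds <- feature_dataset(rbind(c(0, 10), c(0, 0)), c("a", "b"))
#' class_attribute_means(ds)$M1
#' @export
class_attribute_means <- function(ds) {
  stopifnot_dataset(ds)
  idx <- class_indices(ds)
  if (any(lengths(idx) == 0L))
    stop("empty class: every class needs at least one pattern")
  list(M1 = colMeans(ds$x[idx[[1L]], , drop = FALSE]),
       M2 = colMeans(ds$x[idx[[2L]], , drop = FALSE]),
       classes = levels(ds$labels))
}

#' dMeans relevance permutation
#'
#' Ranks all attributes by the difference of their per-class means,
#' `d_i = M1_i - M2_i`, sorted from high to low.  With `mode = "signed"`
#' (the literal rule) the raw difference is sorted; with
#' `mode = "absolute"` its magnitude is sorted, so attributes discriminative
#' in either direction rank high.  Ties are broken by ascending original
#' attribute position, making the ordering fully deterministic.
#'
#' @param ds a [feature_dataset()].
#' @param mode `"signed"` (default) or `"absolute"`.
#' @return An object of class `relevance_permutation`: list with `order`
#'   (a permutation of `1:n`, most relevant first), `d` (the sorted scores
#'   aligned with `order`), `mode`, and `classes` (the C1/C2 assignment the
#'   sign of `d` refers to).
#' @examples
#' ds <- feature_dataset(rbind(c(0, 10), c(0, 0)), c("a", "b"))
#' relevance_permutation(ds)$order  # c(2, 1)
#' @export
relevance_permutation <- function(ds, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  cm <- class_attribute_means(ds)
  d <- cm$M1 - cm$M2
  if (mode == "absolute") d <- abs(d)
  ord <- order(-d, seq_along(d))
  structure(list(order = ord, d = d[ord], mode = mode,
                 classes = cm$classes),
            class = "relevance_permutation")
}

#' @export
print.relevance_permutation <- function(x, n = 10L, ...) {
  k <- min(n, length(x$order))
  cat("relevance_permutation (", x$mode, " mode, ", length(x$order),
      " attributes; C1 = ", x$classes[1L], ")\n", sep = "")
  print(data.frame(rank = seq_len(k), position = x$order[seq_len(k)],
                   d = x$d[seq_len(k)]), row.names = FALSE)
  if (k < length(x$order)) cat("... ", length(x$order) - k, " more\n")
  invisible(x)
}

#' Export a relevance permutation as CSV
#'
#' Writes one row per rank with columns `rank`, `position` (1-based
#' attribute position) and `d` (the sorted relevance score).
#'
#' @param rp a [relevance_permutation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_permutation_csv <- function(rp, path) {
  stopifnot(inherits(rp, "relevance_permutation"))
  utils::write.csv(data.frame(rank = seq_along(rp$order),
                              position = rp$order, d = rp$d),
                   path, row.names = FALSE)
  invisible(path)
}
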