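#' Project a pattern onto its (standard deviation, mean) pair
#'
#' The minimalist representation: a pattern restricted to the selected
#' attribute positions is summarized by two numbers, the sample standard
#' deviation (x coordinate) and the arithmetic mean (y coordinate) of the
#' selected values.  The sample (divisor k-1) standard deviation is used:
#' for two values a, b it equals |a - b| / sqrt(2).
#'
#' @param p numeric pattern vector.
#' @param positions 1-based attribute positions to select; at least 2.
#' @return Named numeric vector `c(x = <sd>, y = <mean>)`.
#' @examples
#' project_pattern(c(67.9, 81.6), 1:2)  # x = 9.6874, y = 74.75
#' @export
project_pattern <- function(p, positions) {
  if (length(positions) < 2L)
    stop("at least 2 attribute positions required (sample sd undefined)")
  if (any(positions < 1L) || any(positions > length(p)))
    stop("attribute positions out of range for this pattern")
  v <- p[positions]
  if (any(!is.finite(v))) stop("pattern has non-finite selected values")
  c(x = stats::sd(v), y = mean(v))
}

#' Hypothesis value (horizontal decision boundary)
#'
#' The decision line of the minimalist classifier: the midpoint between the
#' maximum projected mean of the lower ("minor") class and the minimum
#' projected mean of the upper ("major") class.  The formula applies even
#' when the classes overlap (max(minor) > min(major)).
#'
#' @param minor_means projected means of the minor (lower) class.
#' @param major_means projected means of the major (upper) class.
#' @return The hypothesis value h.
#' @examples
#' hypothesis_value(c(1, 2), c(4, 6))  # 3
#' @export
hypothesis_value <- function(minor_means, major_means) {
  if (length(minor_means) == 0L || length(major_means) == 0L)
    stop("empty class: both mean sets must be non-empty")
  (max(minor_means) + min(major_means)) / 2
}

#' Train a minimalist (MML) classifier
#'
#' Learning phase: the dMeans relevance permutation is computed on the
#' training set, then attributes are added in relevance order ("attribute
#' growth").  At each subset size k in the search schedule every training
#' pattern is projected onto the first k positions; the class whose average
#' projected mean is lower takes the minor (below-line) role, the
#' hypothesis h is the midpoint of [hypothesis_value()], and training
#' accuracy under the mean-versus-h rule is recorded.  The search stops at
#' the first k that separates the classes completely (accuracy 1); if no k
#' does, the smallest k maximizing training accuracy is chosen.
#'
#' @param tr a [feature_dataset()] (the training set).
#' @param mode relevance mode, `"signed"` (default) or `"absolute"`;
#'   see [relevance_permutation()].
#' @param k_schedule integer vector of subset sizes to examine, each in
#'   `[2, n]`; default the full sweep `2:n`.  A coarse grid (e.g.
#'   `c(3, 5, 10, 100, 1000, n)`) is useful for very wide data.
#' @param tie_policy class assigned when a projected mean equals h exactly:
#'   `"below"` (default) or `"above"`.
#' @return An object of class `mml_model`: list with `positions` (the first
#'   k* positions of the permutation), `k_star`, `h`, `side_map` (named
#'   list with the `below` and `above` class labels), `tie_policy`,
#'   `training_accuracy`, `mode`, `n_attributes`, `permutation`, and
#'   `profile` — a data frame with one row per examined k recording
#'   `(k, h, accuracy, fully_separated)`.
#' @examples
#' ds <- feature_dataset(rbind(matrix(0, 3, 4), matrix(10, 3, 4)),
#'                       rep(c("neg", "pos"), each = 3))
#' m <- mml_train(ds)
#' m$k_star; m$h   # 2; 5
#' @export
mml_train <- function(tr, mode = c("signed", "absolute"), k_schedule = NULL,
                      tie_policy = c("below", "above")) {
  stopifnot_dataset(tr)
  mode <- match.arg(mode)
  tie_policy <- match.arg(tie_policy)
  n <- ncol(tr$x)
  m <- nrow(tr$x)
  if (is.null(k_schedule)) k_schedule <- 2:n
  k_schedule <- sort(unique(as.integer(k_schedule)))
  if (any(k_schedule < 2L) || any(k_schedule > n))
    stop("k schedule outside [2, n]")

  rp <- relevance_permutation(tr, mode)
  lev <- levels(tr$labels)
  in_c1 <- tr$labels == lev[1L]
  if (all(in_c1) || !any(in_c1)) stop("empty class")

  # prefix means of every pattern along the permuted attribute order,
  # restricted to the schedule columns: M[i, j] = mean of the first
  # k_schedule[j] most relevant attribute values of pattern i
  xp <- tr$x[, rp$order, drop = FALSE]
  cs <- t(apply(xp, 1L, cumsum))
  M <- sweep(cs[, k_schedule, drop = FALSE], 2L, k_schedule, "/")

  c1max <- apply(M[in_c1, , drop = FALSE], 2L, max)
  c1min <- apply(M[in_c1, , drop = FALSE], 2L, min)
  c1avg <- colMeans(M[in_c1, , drop = FALSE])
  c2max <- apply(M[!in_c1, , drop = FALSE], 2L, max)
  c2min <- apply(M[!in_c1, , drop = FALSE], 2L, min)
  c2avg <- colMeans(M[!in_c1, , drop = FALSE])

  # minor role = class with lower average projected mean (ties -> C1)
  minor_is_c1 <- c1avg <= c2avg
  h <- (ifelse(minor_is_c1, c1max, c2max) +
        ifelse(minor_is_c1, c2min, c1min)) / 2
  separated <- ifelse(minor_is_c1, c1max < c2min, c2max < c1min)

  below <- sweep(M, 2L, h, "<") |
    (sweep(M, 2L, h, "==") & tie_policy == "below")
  is_minor <- outer(in_c1, minor_is_c1, "==")
  acc <- colMeans(below == is_minor)

  pick <- if (any(acc == 1)) which(acc == 1)[1L] else which.max(acc)
  k_star <- k_schedule[pick]
  side <- if (minor_is_c1[pick]) lev else rev(lev)

  structure(list(
    positions = rp$order[seq_len(k_star)],
    k_star = k_star,
    h = h[pick],
    side_map = list(below = side[1L], above = side[2L]),
    tie_policy = tie_policy,
    training_accuracy = acc[pick],
    mode = mode,
    n_attributes = n,
    permutation = rp,
    profile = data.frame(k = k_schedule, h = h, accuracy = acc,
                         fully_separated = separated)
  ), class = "mml_model")
}

#' @export
print.mml_model <- function(x, ...) {
  cat("mml_model: k* = ", x$k_star, " of ", x$n_attributes,
      " attributes (", x$mode, " relevance)\n", sep = "")
  cat("hypothesis h = ", format(x$h), "; below: ", x$side_map$below,
      ", above: ", x$side_map$above, " (ties -> ", x$tie_policy,
      " side)\n", sep = "")
  cat("training accuracy = ", format(x$training_accuracy), "\n", sep = "")
  invisible(x)
}

#' Classify a single pattern
#'
#' Projects the pattern onto the model's selected attribute positions and
#' compares the projected mean with the hypothesis value h.  The decision
#' depends only on the mean coordinate (the boundary is horizontal); a mean
#' exactly equal to h is resolved by the model's tie policy.
#'
#' @param model a trained [mml_train()] model.
#' @param p numeric pattern vector with all attributes the model indexes.
#' @return The assigned class label (character scalar).
#' @export
assign_class <- function(model, p) {
  stopifnot(inherits(model, "mml_model"))
  if (length(p) < max(model$positions))
    stop("pattern is missing attribute positions required by the model")
  y <- project_pattern(p, model$positions)[["y"]]
  if (y < model$h) model$side_map$below
  else if (y > model$h) model$side_map$above
  else model$side_map[[model$tie_policy]]
}

#' Classify a set of patterns
#'
#' Applies the model's decision rule to each row of a pattern matrix (or a
#' [feature_dataset()]), returning the assigned labels together with the
#' (sd, mean) projections used — the projections are what test patterns
#' are plotted from.
#'
#' @param object a trained `mml_model`.
#' @param newdata numeric matrix of patterns (rows), or a
#'   `feature_dataset`.  May have zero rows.
#' @param ... unused.
#' @return A data frame with columns `x` (sd), `y` (mean) and `label`.
#' @export
predict.mml_model <- function(object, newdata, ...) {
  if (is_feature_dataset(newdata)) newdata <- newdata$x
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0),
                      label = character(0)))
  proj <- t(apply(newdata, 1L, project_pattern,
                  positions = object$positions))
  lab <- vapply(seq_len(nrow(newdata)), function(i)
    assign_class(object, newdata[i, ]), character(1L))
  data.frame(x = proj[, "x"], y = proj[, "y"], label = lab)
}

#' Plot the minimalist projection and hypothesis line
#'
#' Renders the classifier's two-dimensional view: training patterns as
#' points at (sample sd, mean), sorted ascending by sd within class along
#' the x axis, the hypothesis as a horizontal line at y = h, and optional
#' test patterns as filled black squares.  Written as a PNG file.
#'
#' @param model a trained `mml_model`.
#' @param tr the training [feature_dataset()].
#' @param test optional matrix/`feature_dataset` of test patterns.
#' @param file output PNG path.
#' @param width,height device size in pixels.
#' @return Invisibly, a list with the plotted `train` data frame
#'   (x, y, label), `test` data frame and `h`.
#' @export
render_projection <- function(model, tr, test = NULL, file,
                              width = 800, height = 600) {
  stopifnot(inherits(model, "mml_model"))
  stopifnot_dataset(tr)
  train_df <- predict(model, tr$x)
  train_df$class <- as.character(tr$labels)
  train_df <- train_df[order(train_df$class, train_df$x), ]
  test_df <- if (is.null(test)) {
    data.frame(x = numeric(0), y = numeric(0), label = character(0))
  } else predict(model, test)

  grDevices::png(file, width = width, height = height)
  on.exit(grDevices::dev.off())
  lev <- levels(tr$labels)
  col <- ifelse(train_df$class == lev[1L], "red", "blue")
  xr <- range(c(train_df$x, test_df$x))
  yr <- range(c(train_df$y, test_df$y, model$h))
  graphics::plot(train_df$x, train_df$y, col = col, pch = 19,
                 xlim = xr, ylim = yr,
                 xlab = "standard deviation", ylab = "mean",
                 main = sprintf("MML projection (k = %d)", model$k_star))
  graphics::abline(h = model$h, col = "magenta", lwd = 2)
  if (nrow(test_df) > 0L)
    graphics::points(test_df$x, test_df$y, pch = 15, col = "black",
                     cex = 1.3)
  graphics::legend("topright", legend = c(lev, "hypothesis"),
                   col = c("red", "blue", "magenta"),
                   pch = c(19, 19, NA), lty = c(NA, NA, 1))
  invisible(list(train = train_df, test = test_df, h = model$h))
}

#' Serialize / restore an MML model as JSON
#'
#' The JSON records the selected 1-based positions, k*, the hypothesis
#' value, the side map, tie policy, relevance mode and training accuracy —
#' everything needed to classify new patterns.
#'
#' @param model a trained `mml_model`.
#' @param path JSON file path.
#' @return `write_mml_model()`: `path`, invisibly. `read_mml_model()`: an
#'   `mml_model` (without the training profile/permutation, which are not
#'   serialized).
#' @export
write_mml_model <- function(model, path) {
  stopifnot(inherits(model, "mml_model"))
  jsonlite::write_json(list(
    k_star = model$k_star,
    positions = model$positions,
    h = model$h,
    side_map = model$side_map,
    tie_policy = model$tie_policy,
    mode = model$mode,
    n_attributes = model$n_attributes,
    training_accuracy = model$training_accuracy
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mml_model
#' @export
read_mml_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    positions = as.integer(o$positions),
    k_star = as.integer(o$k_star),
    h = as.numeric(o$h),
    side_map = list(below = o$side_map$below, above = o$side_map$above),
    tie_policy = o$tie_policy,
    training_accuracy = as.numeric(o$training_accuracy),
    mode = o$mode,
    n_attributes = as.integer(o$n_attributes),
    permutation = NULL,
    profile = NULL
  ), class = "mml_model")
}
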