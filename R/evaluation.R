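#' Two-class confusion matrix
#'
#' Tallies true/false positives and negatives of predicted against true
#' labels, given which class counts as positive (for the hemorrhage
#' pipeline the disease class, IVH, is positive).
#'
#' @param truth vector of true labels (exactly two classes).
#' @param predicted vector of predicted labels, same length, drawn from
#'   the same two classes.
#' @param positive the label of the positive class.
#' @return Object of class `confusion_matrix`: list with integer counts
#'   `TP`, `TN`, `FP`, `FN` and `positive_label`.
#' @examples
#' confusion(c("IVH", "Normal"), c("IVH", "Normal"), positive = "IVH")
#' @export
confusion <- function(truth, predicted, positive) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length")
  classes <- sort(unique(c(truth, positive)))
  if (length(classes) > 2L)
    stop("labels span more than two classes")
  if (!all(predicted %in% classes))
    stop("unknown predicted label(s): ",
         paste(setdiff(predicted, classes), collapse = ", "))
  pos_t <- truth == positive; pos_p <- predicted == positive
  structure(list(TP = sum(pos_t & pos_p), TN = sum(!pos_t & !pos_p),
                 FP = sum(!pos_t & pos_p), FN = sum(pos_t & !pos_p),
                 positive_label = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion_matrix (positive = ", x$positive_label, ")\n", sep = "")
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2L, 2L,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Accuracy, sensitivity and specificity
#'
#' Computes the three standard ratios from a confusion matrix:
#' accuracy = (TP + TN) / total, sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP).  A degenerate denominator (no true
#' positives+false negatives, or no true negatives+false positives) makes
#' the corresponding measure `NA` with a warning — it is reported as
#' missing, never silently as 0.
#'
#' @param cm a [confusion()] result.
#' @return Named numeric vector `c(accuracy, sensitivity, specificity)`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$TN + cm$FP + cm$FN
  if (total == 0L) stop("empty confusion matrix")
  sens <- if (cm$TP + cm$FN == 0L) {
    warning("no positive patterns evaluated: sensitivity undefined")
    NA_real_
  } else cm$TP / (cm$TP + cm$FN)
  spec <- if (cm$TN + cm$FP == 0L) {
    warning("no negative patterns evaluated: specificity undefined")
    NA_real_
  } else cm$TN / (cm$TN + cm$FP)
  c(accuracy = (cm$TP + cm$TN) / total, sensitivity = sens,
    specificity = spec)
}

#' Class imbalance ratio
#'
#' Majority-class count divided by minority-class count (>= 1); e.g.
#' 129 versus 123 patterns gives 1.0488, about 1.05.
#'
#' @param ds a [feature_dataset()].
#' @return The imbalance ratio.
#' @export
imbalance_ratio <- function(ds) {
  stopifnot_dataset(ds)
  cnt <- table(ds$labels)
  if (any(cnt == 0L)) stop("empty class")
  max(cnt) / min(cnt)
}

#' Leave-one-out cross-validation of the MML classifier
#'
#' For each of the m folds the held-out pattern is removed, the relevance
#' permutation and the full MML model are recomputed on the remaining
#' m - 1 patterns only (no leakage: the held-out values never influence
#' the fold's model), and the held-out pattern is classified.  Fold
#' predictions are aggregated into one confusion matrix.  The procedure
#' contains no randomness, so repeated runs are identical.
#'
#' @param ds a [feature_dataset()] with at least 3 patterns and at least 2
#'   patterns per class (each fold must retain both classes).
#' @param positive label of the positive class; default `"IVH"` if
#'   present, otherwise the second (C2) class.
#' @inheritParams mml_train
#' @return Object of class `mml_loocv`: list with `folds` (data frame of
#'   per-fold held-out index, true and predicted label, k* and h),
#'   `confusion`, `metrics`, and `config` (the options used).
#' @examples
#' ds <- feature_dataset(rbind(matrix(0, 3, 4), matrix(10, 3, 4)),
#'                       rep(c("a", "b"), each = 3))
#' mml_loocv(ds)$metrics
#' @export
mml_loocv <- function(ds, mode = c("signed", "absolute"),
                      k_schedule = NULL,
                      tie_policy = c("below", "above"),
                      positive = NULL) {
  stopifnot_dataset(ds)
  mode <- match.arg(mode)
  tie_policy <- match.arg(tie_policy)
  m <- nrow(ds$x)
  if (m < 3L) stop("LOOCV needs at least 3 patterns")
  if (any(table(ds$labels) < 2L))
    stop("each class needs at least 2 patterns (folds must retain both)")
  if (is.null(positive)) {
    lev <- levels(ds$labels)
    positive <- if ("IVH" %in% lev) "IVH" else lev[2L]
  }

  folds <- lapply(seq_len(m), function(i) {
    tr <- dataset_subset(ds, -i)
    model <- mml_train(tr, mode = mode, k_schedule = k_schedule,
                       tie_policy = tie_policy)
    data.frame(fold = i,
               truth = as.character(ds$labels[i]),
               predicted = assign_class(model, ds$x[i, ]),
               k_star = model$k_star, h = model$h)
  })
  folds <- do.call(rbind, folds)
  cm <- confusion(folds$truth, folds$predicted, positive = positive)
  structure(list(folds = folds, confusion = cm,
                 metrics = classification_metrics(cm),
                 config = list(mode = mode, k_schedule = k_schedule,
                               tie_policy = tie_policy,
                               positive = positive)),
            class = "mml_loocv")
}

#' @export
print.mml_loocv <- function(x, ...) {
  cat("mml_loocv over", nrow(x$folds), "folds\n")
  print(round(x$metrics, 4))
  cat("k* range:", min(x$folds$k_star), "-", max(x$folds$k_star), "\n")
  invisible(x)
}

#' Export a LOOCV evaluation
#'
#' Writes the aggregate metrics, confusion counts and configuration as
#' JSON, and optionally the per-fold prediction table as CSV; together
#' they are sufficient to regenerate the run.
#'
#' @param result an [mml_loocv()] result.
#' @param json_path output JSON path.
#' @param csv_path optional output CSV path for the per-fold table.
#' @return `json_path`, invisibly.
#' @export
write_evaluation <- function(result, json_path, csv_path = NULL) {
  stopifnot(inherits(result, "mml_loocv"))
  jsonlite::write_json(list(
    metrics = as.list(result$metrics),
    confusion = result$confusion[c("TP", "TN", "FP", "FN",
                                   "positive_label")],
    config = result$config,
    n_folds = nrow(result$folds),
    k_star = result$folds$k_star
  ), json_path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(csv_path))
    utils::write.csv(result$folds, csv_path, row.names = FALSE)
  invisible(json_path)
}
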