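# Independent brute-force reimplementations used as oracles.  These are
# deliberately naive (explicit loops, literal set definitions) and share no
# code with the package internals.

oracle_class_means <- function(x, labels) {
  lev <- sort(unique(as.character(labels)))
  M <- matrix(NA_real_, 2L, ncol(x))
  for (c in 1:2) for (j in seq_len(ncol(x))) {
    vals <- c()
    for (i in seq_len(nrow(x)))
      if (as.character(labels[i]) == lev[c]) vals <- c(vals, x[i, j])
    M[c, j] <- sum(vals) / length(vals)
  }
  list(M1 = M[1L, ], M2 = M[2L, ])
}

# exhaustive selection sort of the d values, ties to the lowest position
oracle_permutation <- function(x, labels, mode = "signed") {
  cm <- oracle_class_means(x, labels)
  d <- cm$M1 - cm$M2
  if (mode == "absolute") d <- abs(d)
  remaining <- seq_along(d)
  ord <- integer(0)
  while (length(remaining) > 0L) {
    best <- remaining[1L]
    for (j in remaining) if (d[j] > d[best]) best <- j
    ord <- c(ord, best)
    remaining <- setdiff(remaining, best)
  }
  list(order = ord, d = d[ord])
}

# naive attribute-growth training: loop over every k, recompute roles,
# hypothesis and accuracy pattern by pattern
oracle_train <- function(x, labels, mode = "signed", tie = "below") {
  lev <- sort(unique(as.character(labels)))
  ord <- oracle_permutation(x, labels, mode)$order
  best <- NULL
  for (k in 2:ncol(x)) {
    pos <- ord[seq_len(k)]
    means <- apply(x[, pos, drop = FALSE], 1L, mean)
    mu1 <- mean(means[labels == lev[1L]])
    mu2 <- mean(means[labels == lev[2L]])
    minor <- if (mu1 <= mu2) lev[1L] else lev[2L]
    major <- setdiff(lev, minor)
    h <- (max(means[labels == minor]) + min(means[labels == major])) / 2
    correct <- 0L
    for (i in seq_along(means)) {
      pred <- if (means[i] < h) minor
              else if (means[i] > h) major
              else if (tie == "below") minor else major
      if (pred == as.character(labels[i])) correct <- correct + 1L
    }
    acc <- correct / length(means)
    if (is.null(best) || acc > best$acc)
      best <- list(k = k, h = h, acc = acc, minor = minor, major = major)
    if (acc == 1) break
  }
  best
}

oracle_loocv <- function(x, labels, mode = "signed") {
  lev <- sort(unique(as.character(labels)))
  preds <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    fit <- oracle_train(x[-i, , drop = FALSE], labels[-i], mode)
    pos <- oracle_permutation(x[-i, , drop = FALSE],
                              labels[-i], mode)$order[seq_len(fit$k)]
    y <- mean(x[i, pos])
    preds[i] <- if (y < fit$h) fit$minor
                else if (y > fit$h) fit$major else fit$minor
  }
  preds
}

# replicate-padded sliding-window filters, pixel by pixel
oracle_window_filter <- function(img, size, stat) {
  r <- (size - 1L) %/% 2L
  out <- img
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r) {
      ii <- min(max(i + di, 1L), nrow(img))
      jj <- min(max(j + dj, 1L), ncol(img))
      vals <- c(vals, img[ii, jj])
    }
    out[i, j] <- min(max(floor(stat(vals) + 0.5), 0), 255)
  }
  out
}

# literal set-definition morphology: z in output iff the (reflected)
# structuring element translated to z is contained in / intersects A
oracle_erode <- function(mask, se) {
  r <- (nrow(se) - 1L) %/% 2L
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    fits <- TRUE
    for (di in -r:r) for (dj in -r:r) {
      if (se[di + r + 1L, dj + r + 1L] == 0) next
      ii <- i + di; jj <- j + dj
      inside <- ii >= 1L && ii <= nrow(mask) && jj >= 1L && jj <= ncol(mask)
      if (!inside || mask[ii, jj] != 255) { fits <- FALSE }
    }
    if (fits) out[i, j] <- 255
  }
  out
}

oracle_dilate <- function(mask, se) {
  r <- (nrow(se) - 1L) %/% 2L
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    hit <- FALSE
    for (di in -r:r) for (dj in -r:r) {
      if (se[r + 1L - di, r + 1L - dj] == 0) next  # reflected SE
      ii <- i + di; jj <- j + dj
      if (ii >= 1L && ii <= nrow(mask) && jj >= 1L && jj <= ncol(mask) &&
          mask[ii, jj] == 255) hit <- TRUE
    }
    if (hit) out[i, j] <- 255
  }
  out
}

oracle_confusion <- function(truth, predicted, positive) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == positive && predicted[i] == positive) tp <- tp + 1L
    if (truth[i] != positive && predicted[i] != positive) tn <- tn + 1L
    if (truth[i] != positive && predicted[i] == positive) fp <- fp + 1L
    if (truth[i] == positive && predicted[i] != positive) fn <- fn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# small random binary mask over {0, 255}
random_mask <- function(h, w, p = 0.5) {
  matrix(ifelse(stats::runif(h * w) < p, 255, 0), h, w)
}

random_image <- function(h, w) {
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}
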