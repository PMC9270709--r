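#' Train / validation / test split
#'
#' Seeded random partition of `n` items into train, validation and test
#' index sets.  The validation and test sizes are `round(f2 * n)` and
#' `round(f3 * n)`; train takes the remainder, so for n = 200471 at
#' fractions 0.6/0.2/0.2 the sizes are 120283 / 40094 / 40094.
#'
#' @param n number of items (>= 3).
#' @param fractions length-3 numeric summing to 1 (train, validation, test).
#' @param seed RNG seed for the shuffle.
#' @return list with integer index vectors `train`, `validation`, `test`;
#'   disjoint and exhaustive over `1:n`.
#' @export
split_dataset <- function(n, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(n >= 3, length(fractions) == 3)
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1", call. = FALSE)
  n_val <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (n_train < 1 || n_val < 1 || n_test < 1)
    stop("n too small for the requested fractions", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       validation = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

#' Micro and macro F1 over the three sentence classes
#'
#' Per-class precision, recall and F1 are one-vs-rest; undefined ratios
#' (zero denominator) are reported as 0.  Macro F1 is the unweighted mean of
#' the three per-class F1 values; micro F1 pools one-vs-rest counts
#' globally, `TP / (TP + (FP + FN) / 2)`, which for single-label multiclass
#' equals accuracy.
#'
#' @param truth,predicted character vectors of labels in `DELIRIUM_CLASSES`.
#' @return list with `micro_f1`, `macro_f1` and a `per_class` data.frame
#'   (`class`, `precision`, `recall`, `f1`).
#' @export
f1_scores <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  truth <- check_labels(truth, "truth")
  predicted <- check_labels(predicted, "predicted")
  cm <- confusion(truth, predicted)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  micro <- safe_div(sum(tp), sum(tp) + (sum(fp) + sum(fn)) / 2)
  list(micro_f1 = as.numeric(micro),
       macro_f1 = mean(f1),
       per_class = data.frame(class = DELIRIUM_CLASSES,
                              precision = as.numeric(precision),
                              recall = as.numeric(recall),
                              f1 = as.numeric(f1)))
}

#' Confusion matrix and its row/column normalizations
#'
#' Rows are true classes, columns predicted classes, both in the fixed
#' order POSITIVE, NEGATIVE, NEITHER.  Row normalization shows per-class
#' recall on the diagonal; column normalization shows precision.  An empty
#' row or column normalizes to zeros rather than dividing by zero.
#'
#' @inheritParams f1_scores
#' @return `confusion()`: 3x3 integer matrix; `normalize_confusion()`: 3x3
#'   numeric matrix.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  t_f <- factor(check_labels(truth, "truth"), levels = DELIRIUM_CLASSES)
  p_f <- factor(check_labels(predicted, "predicted"),
                levels = DELIRIUM_CLASSES)
  m <- table(truth = t_f, predicted = p_f)
  matrix(as.integer(m), 3, 3,
         dimnames = list(truth = DELIRIUM_CLASSES,
                         predicted = DELIRIUM_CLASSES))
}

#' @rdname confusion
#' @param m 3x3 count matrix from [confusion()].
#' @param axis `"row"` (recall view) or `"column"` (precision view).
#' @export
normalize_confusion <- function(m, axis = c("row", "column")) {
  axis <- match.arg(axis)
  if (axis == "row") {
    s <- rowSums(m)
    out <- m / ifelse(s > 0, s, 1)
    out[s == 0, ] <- 0
  } else {
    s <- colSums(m)
    out <- t(t(m) / ifelse(s > 0, s, 1))
    out[, s == 0] <- 0
  }
  out
}

#' One-vs-rest ROC curve and AUC
#'
#' For a chosen positive class, the class score is thresholded against the
#' binary indicator `truth == positive_class`.  Tied scores are grouped at a
#' single threshold; AUC is the trapezoidal area, which equals the
#' Mann-Whitney U statistic normalized by `n_pos * n_neg` (ties counted
#' half).
#'
#' @param truth label vector.
#' @param scores numeric matrix, one column per class in `DELIRIUM_CLASSES`
#'   order (rows on the probability simplex), or a vector of scores for
#'   `positive_class`.
#' @param positive_class the class to score one-vs-rest.
#' @return list with `roc` (data.frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc_ovr <- function(truth, scores, positive_class) {
  truth <- check_labels(truth, "truth")
  positive_class <- match.arg(positive_class, DELIRIUM_CLASSES)
  if (is.matrix(scores) || is.data.frame(scores)) {
    scores <- as.matrix(scores)[, match(positive_class, DELIRIUM_CLASSES)]
  }
  y <- as.integer(truth == positive_class)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0)
    stop("class absent from truth: ", positive_class, call. = FALSE)
  if (n_neg == 0)
    stop("no negatives for one-vs-rest class: ", positive_class,
         call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  # group ties: cumulative counts at each distinct threshold
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(yy); fp <- cumsum(1 - yy)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  thr <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = as.numeric(auc))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the evaluation units (rows of `data`, or elements of a vector)
#' with replacement `n_boot` times and reports the 2.5/97.5 percentile
#' interval of `metric_fn` together with the point estimate on the original
#' data.  Resamples on which the metric is undefined (error or non-finite)
#' are dropped; if more than 10% are undefined the call errors.
#'
#' @param metric_fn function of one resampled `data` returning one number.
#' @param data vector or data.frame of evaluation units.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return list with `point`, `ci_low`, `ci_high`, `n_boot`, `seed`.
#' @export
bootstrap_ci <- function(metric_fn, data, n_boot = 1000L, seed = 1L,
                         conf = 0.95) {
  stopifnot(n_boot >= 100)
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  stopifnot(n >= 1)
  take <- function(idx) if (is.data.frame(data))
    data[idx, , drop = FALSE] else data[idx]
  point <- metric_fn(data)
  stats <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(as.numeric(metric_fn(take(idx))),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  bad <- !is.finite(stats)
  if (mean(bad) > 0.10)
    stop(sprintf("metric undefined on %.0f%% of bootstrap resamples",
                 100 * mean(bad)), call. = FALSE)
  qs <- quantile(stats[!bad], c((1 - conf) / 2, 1 - (1 - conf) / 2),
                 names = FALSE, type = 7)
  list(point = as.numeric(point), ci_low = qs[1], ci_high = qs[2],
       n_boot = as.integer(n_boot), seed = as.integer(seed))
}

#' Pairwise per-category interrater agreement
#'
#' For each category `c`, positive specific agreement between two raters:
#' `2 * |a = c & b = c| / (|a = c| + |b = c|)` — the between-rater F1 for
#' that category.  Categories used by neither rater are reported as `NA`.
#'
#' @param labels_a,labels_b label vectors over the same sentences.
#' @return named numeric vector over `DELIRIUM_CLASSES` (values in `[0, 1]`
#'   or `NA` when a category is unused by both raters).
#' @export
pairwise_ira <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length", call. = FALSE)
  labels_a <- check_labels(labels_a, "labels_a")
  labels_b <- check_labels(labels_b, "labels_b")
  out <- vapply(DELIRIUM_CLASSES, function(cl) {
    na <- sum(labels_a == cl); nb <- sum(labels_b == cl)
    if (na + nb == 0) return(NA_real_)
    2 * sum(labels_a == cl & labels_b == cl) / (na + nb)
  }, numeric(1))
  setNames(out, DELIRIUM_CLASSES)
}
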