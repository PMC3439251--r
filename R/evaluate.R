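# Evaluation: ROC/AUC by the rank formulation, threshold metrics
# (precision, recall, F-score, specificity, MCC), the max-F operating
# point, repeated stratified cross-validation, and the nearest-neighbour
# comparison baseline.

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formulation with half credit for
#' ties, which equals the trapezoidal area under the tie-aware ROC curve.
#'
#' @param scores Numeric scores (larger = more positive-like).
#' @param labels Logical (or 0/1) vector; `TRUE` marks a positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Tie-aware ROC curve
#'
#' @inheritParams roc_auc
#' @return Data.frame with columns `threshold`, `fpr`, `tpr` (descending
#'   thresholds, anchored at (0,0) and (1,1)).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(labels & scores >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(!labels & scores >= t) / n0, numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Confusion counts at a score threshold
#'
#' Predicts positive when `score >= threshold`.
#'
#' @inheritParams roc_auc
#' @param threshold Decision cutoff.
#' @return Named integer vector `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(scores, labels, threshold) {
  labels <- as.logical(labels)
  pred <- scores >= threshold
  c(TP = sum(pred & labels), FP = sum(pred & !labels),
    TN = sum(!pred & !labels), FN = sum(!pred & labels))
}

#' Threshold metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, recall/sensitivity `TP/(TP+FN)`, F-score
#' `2PR/(P+R)`, specificity `TN/(TN+FP)` and the Matthews correlation
#' coefficient. A metric whose denominator is zero is reported as 0 and
#' listed in the `zero_denominator` attribute rather than raising an
#' error.
#'
#' @param counts Named numeric vector or list with `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric vector `precision`, `recall`, `sensitivity`, `F`,
#'   `specificity`, `MCC`.
#' @export
threshold_metrics <- function(counts) {
  counts <- as.numeric(unlist(counts)[c("TP", "FP", "TN", "FN")])
  names(counts) <- c("TP", "FP", "TN", "FN")
  stopifnot(!anyNA(counts), all(counts >= 0))
  tp <- counts["TP"]; fp <- counts["FP"]; tn <- counts["TN"]; fn <- counts["FN"]
  flagged <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { flagged <<- c(flagged, name); 0 } else num / den
  }
  p <- safe(tp, tp + fp, "precision")
  r <- safe(tp, tp + fn, "recall")
  f <- safe(2 * p * r, p + r, "F")
  spec <- safe(tn, tn + fp, "specificity")
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- safe(tp * tn - fp * fn, mcc_den, "MCC")
  out <- c(precision = unname(p), recall = unname(r), sensitivity = unname(r),
           F = unname(f), specificity = unname(spec), MCC = unname(mcc))
  attr(out, "zero_denominator") <- flagged
  out
}

#' Operating point maximizing the F-score
#'
#' Evaluates every observed score as a candidate threshold (predicting
#' positive at or above it) and returns the lowest threshold attaining the
#' maximum F-score.
#'
#' @inheritParams roc_auc
#' @return List with `threshold`, `counts` (confusion counts at the
#'   threshold) and `F`.
#' @export
max_f_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  cand <- sort(unique(scores))
  f <- vapply(cand, function(t)
    unname(threshold_metrics(confusion_counts(scores, labels, t))["F"]),
    numeric(1))
  best <- cand[which(f >= max(f) - 1e-12)[1]]
  list(threshold = best, counts = confusion_counts(scores, labels, best),
       F = max(f))
}

#' Repeated stratified cross-validation
#'
#' For each repeat (seeded `seed + repeat - 1`) records are assigned to
#' stratified folds; the model builder is trained on the k-1 training
#' folds only (including any internal SVM calibration split and PWM
#' background fitting) and scores the held-out fold. Held-out scores are
#' pooled within a repeat; AUC and the metrics at the max-F threshold are
#' computed per repeat and summarized as mean and standard deviation
#' across repeats.
#'
#' @param model_builder Function taking a training subset of `data` and
#'   returning a scoring function (test subset -> numeric scores, larger =
#'   more stable-like).
#' @param data A [stability_data()] object, or a data.frame with a `label`
#'   column.
#' @param folds Number of folds (>= 2).
#' @param repeats Number of repeated splits.
#' @param seed Base integer seed.
#' @return Object of class `cv_report`: `summary` (data.frame metric x
#'   mean/sd), `per_repeat`, `thresholds`, `folds`, `repeats`.
#' @export
cross_validate <- function(model_builder, data, folds = 10L, repeats = 5L,
                           seed = 1L) {
  stopifnot(folds >= 2L, repeats >= 1L)
  if (inherits(data, "stability_data")) {
    labels <- as.character(data$labels)
    ids <- names(data$labels)
    take <- function(idx) subset_stability_data(data, ids[idx])
  } else if (is.data.frame(data) && "label" %in% names(data)) {
    labels <- as.character(data$label)
    take <- function(idx) data[idx, , drop = FALSE]
  } else stop("data must be a stability_data object or a data.frame with a 'label' column")
  n <- length(labels)
  per_repeat <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + r - 1L)
    fold <- NULL
    for (attempt in 1:10) {
      cand <- stratified_folds(labels, folds)
      ok <- all(vapply(seq_len(folds), function(k)
        length(unique(labels[cand == k])) == 2L || sum(cand == k) <= 1L,
        logical(1)))
      if (ok) { fold <- cand; break }
    }
    if (is.null(fold))
      stop("could not build folds containing both classes after 10 attempts")
    scores <- numeric(n)
    for (k in seq_len(folds)) {
      test_idx <- which(fold == k)
      train_idx <- which(fold != k)
      scorer <- model_builder(take(train_idx))
      scores[test_idx] <- scorer(take(test_idx))
    }
    pos <- labels == "stable"
    mf <- max_f_threshold(scores, pos)
    m <- threshold_metrics(mf$counts)
    per_repeat[[r]] <- c(AUC = roc_auc(scores, pos), `F` = unname(m["F"]),
                         MCC = unname(m["MCC"]),
                         sensitivity = unname(m["sensitivity"]),
                         specificity = unname(m["specificity"]),
                         threshold = mf$threshold)
  }
  pr <- do.call(rbind, per_repeat)
  metrics <- c("AUC", "F", "MCC", "sensitivity", "specificity")
  summary <- data.frame(metric = metrics,
                        mean = colMeans(pr[, metrics, drop = FALSE]),
                        sd = apply(pr[, metrics, drop = FALSE], 2, stats::sd),
                        row.names = NULL)
  if (repeats == 1L) summary$sd <- 0
  structure(list(summary = summary, per_repeat = pr,
                 thresholds = pr[, "threshold"], folds = folds,
                 repeats = repeats, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(x$folds, "-fold cross-validation, ", x$repeats, " repeat(s)\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s mean %.4f  sd %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Model builder for the cross-validation harness
#'
#' Returns a closure suitable for [cross_validate()]: given a training
#' [stability_data()] subset it fits a [stability_model()] of the
#' requested variant (training the SVM and PWM components on the training
#' subset only) and returns a function scoring a test subset.
#'
#' @inheritParams stability_model
#' @return Function: training `stability_data` -> (test `stability_data`
#'   -> numeric scores).
#' @export
stability_model_builder <- function(variant = c("bn_svm", "bn", "svm"),
                                    pwm_windows = NULL,
                                    control = em_control()) {
  variant <- match.arg(variant)
  function(train) {
    fit <- stability_model(labels = train$labels,
                           sequences = train$sequences,
                           annotations = train$annotations,
                           pwm_windows = pwm_windows, variant = variant,
                           control = control)
    function(test) predict(fit, newdata = test, type = "prob")
  }
}

#' Nearest-neighbour comparison baseline
#'
#' Stores a training feature matrix and labels; queries are scored as
#' `D- - D+` under the 1-cosine distance: the minimum distance to a
#' negative training sample minus the minimum distance to a positive one,
#' so larger scores are more positive-like.
#'
#' @param x Numeric training matrix (rows = samples).
#' @param labels Logical vector; `TRUE` marks a positive sample.
#' @return Object of class `nn_baseline`.
#' @export
nn_baseline <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.logical(labels)
  stopifnot(nrow(x) == length(labels))
  if (!any(labels) || all(labels))
    stop("training set must contain both classes")
  norms <- sqrt(rowSums(x^2))
  if (any(norms == 0)) stop("zero-norm training vector")
  structure(list(x = x / norms, labels = labels), class = "nn_baseline")
}

#' @rdname nn_baseline
#' @param baseline An `nn_baseline`.
#' @param query Numeric query vector (or matrix of queries).
#' @return Numeric score(s) `D- - D+`.
#' @export
nn_score <- function(baseline, query) {
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  norms <- sqrt(rowSums(query^2))
  if (any(norms == 0)) stop("zero-norm query vector")
  q <- query / norms
  sim <- q %*% t(baseline$x)              # cosine similarity
  d <- 1 - sim
  dpos <- apply(d[, baseline$labels, drop = FALSE], 1, min)
  dneg <- apply(d[, !baseline$labels, drop = FALSE], 1, min)
  as.numeric(dneg - dpos)
}
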