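#' Stratified train/test split
#'
#' Partitions samples into a training and a test set, preserving the class
#' proportions: each class is split `fraction` / `1 - fraction` with the
#' training count taken as `floor(fraction * n_class)` (so partitions can
#' differ by at most one sample per class), and assignment within class is
#' random given `seed`.
#'
#' @param labels factor or character vector of class labels.
#' @param fraction training fraction, in (0, 1).
#' @param seed integer seed; identical seeds give identical plans.
#' @return Object of class `SplitPlan`: list with integer index vectors
#'   `train` and `test` (disjoint, union = all samples), plus `seed`.
#' @export
stratified_split <- function(labels, fraction = 0.5, seed = 1) {
  labels <- as.character(labels)
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)")
  counts <- table(labels)
  if (length(counts) < 2) stop("both classes must be present")
  if (any(counts < 2)) {
    stop("class(es) with fewer than 2 samples: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  with_seed(seed, {
    train <- integer(0)
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      n_train <- floor(fraction * length(idx))
      train <- c(train, sample(idx, n_train))
    }
    train <- sort(train)
    structure(
      list(train = train, test = setdiff(seq_along(labels), train),
           seed = as.integer(seed)),
      class = "SplitPlan"
    )
  })
}

#' Classifier evaluation: confusion matrix, sensitivity/specificity, ROC/AUC
#'
#' Predictions are `sign(score)` with zero assigned to the positive class
#' (tumor). The ROC curve sweeps a threshold across the unique scores; AUC
#' is the Mann-Whitney rank statistic — the fraction of positive/negative
#' pairs ranked correctly, with half credit for ties.
#'
#' @param y_true labels (`+/-1` or `tumor`/`normal`); both classes required.
#' @param scores real-valued decision scores, higher = more tumor-like.
#' @return Object of class `EvalReport`: `confusion` (named TP/FN/FP/TN),
#'   `accuracy`, `sensitivity` (= TP/(TP+FN)), `specificity` (= TN/(TN+FP)),
#'   `roc` (data.frame `fpr`, `tpr`, `threshold`) and `auc`.
#' @export
evaluate_scores <- function(y_true, scores) {
  y <- as_pm1(y_true)
  if (length(y) != length(scores)) stop("labels and scores differ in length")
  if (length(unique(y)) < 2) stop("need at least one positive and one negative")
  pred <- ifelse(scores >= 0, 1, -1)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == -1 & y == 1)
  fp <- sum(pred == 1 & y == -1); tn <- sum(pred == -1 & y == -1)

  pos <- scores[y == 1]; neg <- scores[y == -1]
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(pos >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(neg >= t), numeric(1))
  )

  structure(
    list(confusion = c(TP = tp, FN = fn, FP = fp, TN = tn),
         accuracy = (tp + tn) / length(y),
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         roc = roc[, c("fpr", "tpr", "threshold")],
         auc = auc),
    class = "EvalReport"
  )
}

#' @export
print.EvalReport <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf(
    paste0("EvalReport: accuracy %.3f, sensitivity %.3f, specificity %.3f, ",
           "AUC %.3f\n  confusion: TP=%d FN=%d FP=%d TN=%d\n"),
    x$accuracy, x$sensitivity, x$specificity, x$auc,
    cm["TP"], cm["FN"], cm["FP"], cm["TN"]
  ))
  invisible(x)
}

#' Stratified k-fold cross-validation of the linear SVM
#'
#' Samples are dealt into `k` stratified folds (per class, a seeded random
#' order dealt round-robin). For each fold a model is trained on the
#' complement — feature standardization recomputed from the training fold
#' only — and scores the held-out fold; the pooled out-of-fold scores feed a
#' single [evaluate_scores()] report.
#'
#' @param x numeric sample-by-feature matrix.
#' @param y labels (`+/-1` or `tumor`/`normal`).
#' @param k number of folds; reduced with a warning if a class has fewer
#'   than `k` samples. `k < 2` is an error.
#' @param seed integer seed for fold assignment.
#' @param C,standardize,tol passed to [train_svm()].
#' @return An `EvalReport` with extra fields `folds` (per-sample fold id)
#'   and `scores` (pooled out-of-fold decision values).
#' @export
cross_validate <- function(x, y, k = 10, seed = 1, C = 1, standardize = TRUE,
                           tol = 1e-6) {
  x <- as.matrix(x)
  yv <- as_pm1(y)
  if (k < 2) stop("'k' must be at least 2")
  min_class <- min(table(yv))
  if (min_class < k) {
    warning("reducing k from ", k, " to ", min_class,
            " (smallest class size)")
    k <- min_class
  }
  folds <- integer(length(yv))
  with_seed(seed, {
    for (cl in c(-1, 1)) {
      idx <- sample(which(yv == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  scores <- numeric(length(yv))
  for (f in seq_len(k)) {
    hold <- folds == f
    model <- train_svm(x[!hold, , drop = FALSE], yv[!hold], C = C,
                       standardize = standardize, tol = tol)
    scores[hold] <- decision_values(model, x[hold, , drop = FALSE])
  }
  report <- evaluate_scores(yv, scores)
  report$folds <- folds
  report$scores <- scores
  report
}

#' Write an evaluation report (JSON) and its ROC points (TSV)
#'
#' @param report an `EvalReport`.
#' @param json_path,roc_path output paths; either may be `NULL` to skip.
#' @return Invisibly, the written paths.
#' @export
write_eval_report <- function(report, json_path = NULL, roc_path = NULL) {
  stopifnot(inherits(report, "EvalReport"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(confusion = as.list(report$confusion), accuracy = report$accuracy,
           sensitivity = report$sensitivity, specificity = report$specificity,
           auc = report$auc),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  if (!is.null(roc_path)) {
    write.table(report$roc, roc_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(json_path, roc_path))
}
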