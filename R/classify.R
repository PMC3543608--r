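#' Percentage of positive activity (PPA) per peptide
#'
#' Counts the binding events of every peptide and expresses them as a
#' percentage of the highest per-peptide event count, which defines the
#' 100 percent reference.
#'
#' @param binary a `binary_binding_matrix` with at least one binding
#'   event.
#' @return object of class `ppa_labels`: list with `peptide_ids`,
#'   `event_counts`, `ppa`; `activity` and `threshold_percent` are filled
#'   in by [assign_activity()].
#' @export
compute_ppa <- function(binary) {
  stopifnot(inherits(binary, "binary_binding_matrix"))
  counts <- colSums(binary$bits)
  if (max(counts) == 0)
    stop("cannot compute PPA: the matrix has no binding events")
  structure(list(peptide_ids = colnames(binary$bits),
                 event_counts = unname(counts),
                 ppa = unname(100 * counts / max(counts)),
                 activity = NULL, threshold_percent = NULL),
            class = "ppa_labels")
}

#' Label peptides as binders by a PPA threshold
#'
#' A peptide is active (1) iff its PPA is strictly greater than
#' `threshold_percent`; the boundary value itself is inactive. Lower
#' thresholds therefore give monotonically more positives.
#'
#' @param ppa a `ppa_labels` object from [compute_ppa()].
#' @param threshold_percent threshold in `[0, 100)`; default 30, which
#'   balances positives and negatives on a broad binding panel.
#' @return the `ppa_labels` object with `activity`, `threshold_percent`
#'   and a `stats` element (`n_pos`, `n_neg`, `pct_pos`, with `pct_pos`
#'   rounded to integer for reporting).
#' @export
assign_activity <- function(ppa, threshold_percent = 30) {
  stopifnot(inherits(ppa, "ppa_labels"))
  if (threshold_percent < 0 || threshold_percent >= 100)
    stop("'threshold_percent' must be in [0, 100)")
  act <- as.integer(ppa$ppa > threshold_percent)
  ppa$activity <- act
  ppa$threshold_percent <- threshold_percent
  ppa$stats <- list(n_pos = sum(act == 1L), n_neg = sum(act == 0L),
                    pct_pos = as.integer(round(100 * mean(act))))
  ppa
}

#' @export
print.ppa_labels <- function(x, ...) {
  cat(sprintf("ppa_labels: %d peptides, max event count %d\n",
              length(x$peptide_ids), max(x$event_counts)))
  if (!is.null(x$activity))
    cat(sprintf("  threshold %g%%: %d positives / %d negatives (%d%% positive)\n",
                x$threshold_percent, x$stats$n_pos, x$stats$n_neg,
                x$stats$pct_pos))
  invisible(x)
}

#' Random subsampling splits with a fixed train:test ratio per class
#'
#' Each split divides the positives into train and test in the given
#' ratio without replacement, and the negatives likewise, so class
#' balance is preserved on both sides. Splits are seeded and disjoint
#' within themselves (train and test partition the data).
#'
#' @param labels 0/1 integer vector.
#' @param n_splits number of random splits (default 3).
#' @param train_ratio,test_ratio integers giving the train:test ratio
#'   (default 4:1).
#' @param seed integer seed.
#' @return list of `n_splits` lists with integer index vectors `train`
#'   and `test`.
#' @export
subsample_splits <- function(labels, n_splits = 3L, train_ratio = 4L,
                             test_ratio = 1L, seed = 1L) {
  stopifnot(all(labels %in% c(0L, 1L)))
  per_class <- split(seq_along(labels), labels)
  if (length(per_class) < 2L) stop("both classes must be present")
  denom <- train_ratio + test_ratio
  if (any(lengths(per_class) < denom))
    stop("each class needs at least ", denom, " members for a ",
         train_ratio, ":", test_ratio, " split")
  set.seed(seed)
  lapply(seq_len(n_splits), function(s) {
    te <- unlist(lapply(per_class, function(idx) {
      n_test <- max(1L, floor(length(idx) * test_ratio / denom))
      sample(idx, n_test)
    }), use.names = FALSE)
    list(train = sort(setdiff(seq_along(labels), te)), test = sort(te))
  })
}

#' Confusion-matrix performance metrics
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return list with `precision`, `recall`, `specificity`, `accuracy`,
#'   `f_measure` (harmonic mean of precision and recall), and the counts.
#'   Metrics with a zero denominator are `NA`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  p <- div(tp, tp + fp)
  r <- div(tp, tp + fn)
  f1 <- if (is.na(p) || is.na(r) || (p + r) == 0) NA_real_ else
    2 * p * r / (p + r)
  list(precision = p, recall = r,
       specificity = div(tn, tn + fp),
       accuracy = div(tp + tn, tp + tn + fp + fn),
       f_measure = f1, tp = tp, fp = fp, tn = tn, fn = fn)
}

auc_score <- function(labels, scores) {
  if (length(unique(labels)) < 2L || any(!is.finite(scores)))
    return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c("0", "1"), direction = "<",
                                 quiet = TRUE)))
}

default_params <- function(algorithm) {
  switch(algorithm,
         svm_rbf = list(gamma = 0.5, cost = 2.0),
         random_forest = list(ntree = 500L),
         naive_bayes = list(),
         ann = list(size = 10L, decay = 1e-3, maxit = 300L),
         knn = list(k = 5L),
         stop("unknown algorithm '", algorithm, "'"))
}

fit_predict <- function(algorithm, xtr, ytr, xte, params) {
  yf <- factor(ytr, levels = c(0L, 1L))
  switch(algorithm,
    svm_rbf = {
      fit <- e1071::svm(xtr, yf, kernel = "radial", gamma = params$gamma,
                        cost = params$cost, scale = FALSE)
      pr <- stats::predict(fit, xte, decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      # orient the margin so larger = more positive-class
      if (grepl("^0/", colnames(attr(pr, "decision.values"))[1])) dv <- -dv
      list(pred = as.integer(as.character(pr)), score = dv)
    },
    random_forest = {
      fit <- randomForest::randomForest(xtr, yf, ntree = params$ntree)
      prob <- stats::predict(fit, xte, type = "prob")[, "1"]
      list(pred = as.integer(prob > 0.5), score = prob)
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(as.data.frame(xtr), yf)
      prob <- stats::predict(fit, as.data.frame(xte), type = "raw")[, "1"]
      list(pred = as.integer(prob > 0.5), score = prob)
    },
    ann = {
      fit <- nnet::nnet(xtr, as.numeric(as.character(yf)),
                        size = params$size, decay = params$decay,
                        maxit = params$maxit, entropy = TRUE, trace = FALSE,
                        MaxNWts = (ncol(xtr) + 2L) * params$size + 1L)
      prob <- drop(stats::predict(fit, xte))
      list(pred = as.integer(prob > 0.5), score = prob)
    },
    knn = {
      pr <- class::knn(xtr, xte, yf, k = params$k, prob = TRUE)
      pwin <- attr(pr, "prob")
      prob <- ifelse(pr == "1", pwin, 1 - pwin)
      list(pred = as.integer(as.character(pr)), score = prob)
    },
    stop("unknown algorithm '", algorithm, "'"))
}

#' Evaluate a classifier over train/test splits
#'
#' Fits the requested algorithm on each split's training set, scores its
#' test set, and reports precision, recall, specificity, accuracy,
#' F-measure and AUC per split plus their averages. SVM uses the radial
#' basis kernel with gamma = 0.5 and C = 2.0 by default; other
#' algorithms use conventional defaults (500 trees, k = 5, one hidden
#' layer of 10 logistic units), all overridable through `params` and
#' echoed in the report.
#'
#' @param features numeric feature matrix, rows aligned to `labels`.
#' @param labels 0/1 vector.
#' @param splits list of train/test index pairs from
#'   [subsample_splits()].
#' @param algorithm one of `"svm_rbf"`, `"random_forest"`,
#'   `"naive_bayes"`, `"ann"`, `"knn"`.
#' @param params named list of algorithm parameters; unset entries take
#'   the defaults above.
#' @param seed integer seed for the stochastic learners (per-split seeds
#'   are derived from it).
#' @return object of class `metrics_report`: `per_split` data.frame,
#'   `average` named vector, `algorithm`, `params`.
#' @export
evaluate <- function(features, labels, splits, algorithm, params = list(),
                     seed = 1L) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  params <- utils::modifyList(default_params(algorithm), params)
  rows <- lapply(seq_along(splits), function(s) {
    sp <- splits[[s]]
    set.seed(seed + s)
    fp <- fit_predict(algorithm, features[sp$train, , drop = FALSE],
                      labels[sp$train], features[sp$test, , drop = FALSE],
                      params)
    truth <- labels[sp$test]
    m <- confusion_metrics(tp = sum(fp$pred == 1 & truth == 1),
                           fp = sum(fp$pred == 1 & truth == 0),
                           tn = sum(fp$pred == 0 & truth == 0),
                           fn = sum(fp$pred == 0 & truth == 1))
    m$auc <- auc_score(truth, fp$score)
    c(split = s, unlist(m))
  })
  per_split <- as.data.frame(do.call(rbind, rows))
  metric_cols <- c("precision", "recall", "specificity", "accuracy",
                   "f_measure", "auc")
  structure(list(per_split = per_split,
                 average = colMeans(per_split[, metric_cols, drop = FALSE],
                                    na.rm = TRUE),
                 algorithm = algorithm, params = params,
                 validation = "random_subsampling"),
            class = "metrics_report")
}

#' Leave-one-out cross-validation of a classifier
#'
#' Fits n models, each leaving one item out, pools the n single-item
#' predictions into one confusion matrix and computes the metrics (AUC
#' from the pooled scores).
#'
#' @inheritParams evaluate
#' @return a `metrics_report` with the pooled confusion counts in
#'   `per_split` (one row) and the pooled metrics in `average`.
#' @export
loocv_evaluate <- function(features, labels, algorithm, params = list(),
                           seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(n == length(labels))
  if (n < 3L) stop("LOOCV needs at least 3 items")
  params <- utils::modifyList(default_params(algorithm), params)
  pred <- integer(n); score <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(seed + i)
    fp <- fit_predict(algorithm, features[-i, , drop = FALSE], labels[-i],
                      features[i, , drop = FALSE], params)
    pred[i] <- fp$pred; score[i] <- fp$score
  }
  m <- confusion_metrics(tp = sum(pred == 1 & labels == 1),
                         fp = sum(pred == 1 & labels == 0),
                         tn = sum(pred == 0 & labels == 0),
                         fn = sum(pred == 0 & labels == 1))
  m$auc <- auc_score(labels, score)
  per <- as.data.frame(t(c(split = 1, unlist(m))))
  metric_cols <- c("precision", "recall", "specificity", "accuracy",
                   "f_measure", "auc")
  structure(list(per_split = per,
                 average = unlist(m[metric_cols]),
                 algorithm = algorithm, params = params,
                 validation = "loocv"),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report (%s, %s):\n", x$algorithm, x$validation))
  print(round(x$average, 4))
  invisible(x)
}
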