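#' Resampled group-wise network indices
#'
#' A single group yields a single group-wise network, hence a single value
#' of any univariate index -- too little for classification.  Resampling
#' draws `floor(K * rate)` distinct subjects without replacement, rebuilds
#' the group-wise network of the subset, and records the index, `n` times.
#'
#' @param group an [suv_table].
#' @param index_fn function from [suv_table] to scalar, e.g. from
#'   [network_index_fn()].
#' @param n number of resamples, default 5000.
#' @param rate fraction of subjects retained per resample, default 0.5.
#' @param seed integer seed.
#' @return Object of class `resample_set`: list with `values` (length `n`),
#'   `group`, `rate`, `n`, `seed`.
#' @export
resample_networks <- function(group, index_fn, n = 5000L, rate = 0.5,
                              seed = NULL) {
  stopifnot(inherits(group, "suv_table"), is.function(index_fn))
  K <- nrow(group$values)
  k <- floor(K * rate)
  if (k < 3L)
    stop("floor(K * rate) = ", k, " subjects per resample; need at least 3")
  if (!is.null(seed)) set.seed(seed)
  values <- vapply(seq_len(n), function(b) {
    index_fn(suv_subset(group, sample.int(K, k)))
  }, numeric(1))
  structure(list(values = values, group = group$group, rate = rate,
                 n = as.integer(n), seed = seed),
            class = "resample_set")
}

#' @export
print.resample_set <- function(x, ...) {
  cat(sprintf("resample_set: %d resampled networks of group '%s' (rate %.2f)\n",
              x$n, x$group, x$rate))
  cat(sprintf("  index mean %.6g, sd %.3g\n", mean(x$values),
              stats::sd(x$values)))
  invisible(x)
}

#' Leave-one-out SVM classification of univariate network indices
#'
#' Trains a linear-kernel support vector machine (unit regularization cost)
#' on a single index feature and evaluates it by leave-one-out
#' cross-validation: for every sample, an SVM trained on all other samples
#' predicts its label.  The feature is standardized using the training fold
#' only.  With three classes, one-vs-rest machines are trained per fold and
#' the predicted label is the class with the largest decision score;
#' sensitivity, specificity and AUC are then macro-averaged one-vs-rest.
#'
#' @param features either a list of [resample_set] objects (labels taken
#'   from their group fields) or a numeric vector of index values.
#' @param labels class labels, required when `features` is a numeric
#'   vector.
#' @param positive label treated as the positive class for two-class
#'   sensitivity/specificity/ROC; defaults to the first label encountered.
#' @param cost SVM regularization constant, default 1.
#' @return Object of class `classification_report`: accuracy, sensitivity,
#'   specificity, auc, `roc` (two-class: matrix of (FPR, TPR) points from
#'   (0,0) to (1,1); three-class: list of per-class one-vs-rest matrices),
#'   `labels`, `predicted`, `scores`.
#' @examples
#' r <- loo_svm(c(rnorm(20), rnorm(20, 3)), rep(c("a", "b"), each = 20))
#' r
#' @export
loo_svm <- function(features, labels = NULL, positive = NULL, cost = 1) {
  if (is.list(features) &&
      all(vapply(features, inherits, logical(1), "resample_set"))) {
    labels <- rep(vapply(features, `[[`, character(1), "group"),
                  vapply(features, function(s) length(s$values), integer(1)))
    features <- unlist(lapply(features, `[[`, "values"))
  }
  x <- as.numeric(features)
  labels <- as.character(labels)
  if (length(x) != length(labels))
    stop("features and labels have different lengths")
  classes <- unique(labels)
  L <- length(classes)
  if (L < 2L) stop("classification needs at least 2 classes")
  if (L > 3L) stop("at most 3 classes are supported")
  if (any(table(labels) < 4L)) stop("each class needs at least 4 samples")
  if (is.null(positive)) positive <- classes[1L]
  if (!positive %in% classes) stop("`positive` is not one of the class labels")
  n <- length(x)

  # Per left-out sample: an SVM trained on the rest provides the predicted
  # label and decision scores.  With two classes a single machine suffices;
  # with three, the multiclass SVM votes over its one-vs-one machines (a
  # single linear machine on one feature cannot isolate the middle class)
  # and each class's score is the sum of its signed pairwise decisions.
  scores <- matrix(NA_real_, n, L, dimnames = list(NULL, classes))
  predicted <- character(n)
  for (i in seq_len(n)) {
    xtr <- x[-i]; ytr <- labels[-i]
    mu <- mean(xtr); s <- stats::sd(xtr)
    if (s == 0) s <- 1
    xi <- matrix((x[i] - mu) / s, ncol = 1L)
    xtr <- matrix((xtr - mu) / s, ncol = 1L)
    fit <- e1071::svm(xtr, factor(ytr, levels = classes), kernel = "linear",
                      cost = cost, scale = FALSE)
    pr <- stats::predict(fit, xi, decision.values = TRUE)
    predicted[i] <- as.character(pr)
    dv <- attr(pr, "decision.values")  # columns named "first/second"
    for (cl in classes) {
      pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
      sc <- 0
      for (k in seq_along(pairs)) {
        if (pairs[[k]][1L] == cl) sc <- sc + dv[1L, k]
        if (pairs[[k]][2L] == cl) sc <- sc - dv[1L, k]
      }
      scores[i, cl] <- sc
    }
  }
  accuracy <- mean(predicted == labels)

  one_vs_rest <- function(cl) {
    truth <- labels == cl
    pred <- predicted == cl
    sens <- sum(pred & truth) / sum(truth)
    spec <- sum(!pred & !truth) / sum(!truth)
    rc <- pROC::roc(response = factor(truth, levels = c(FALSE, TRUE)),
                    predictor = scores[, cl], levels = c(FALSE, TRUE),
                    direction = "<", quiet = TRUE)
    pts <- cbind(fpr = 1 - rc$specificities, tpr = rc$sensitivities)
    pts <- pts[order(pts[, "fpr"], pts[, "tpr"]), , drop = FALSE]
    list(sens = sens, spec = spec, auc = as.numeric(pROC::auc(rc)), roc = pts)
  }
  if (L == 2L) {
    m <- one_vs_rest(positive)
    report <- list(accuracy = accuracy, sensitivity = m$sens,
                   specificity = m$spec, auc = m$auc, roc = m$roc,
                   labels = classes, positive = positive,
                   predicted = predicted, scores = scores)
  } else {
    ms <- lapply(classes, one_vs_rest)
    report <- list(accuracy = accuracy,
                   sensitivity = mean(vapply(ms, `[[`, numeric(1), "sens")),
                   specificity = mean(vapply(ms, `[[`, numeric(1), "spec")),
                   auc = mean(vapply(ms, `[[`, numeric(1), "auc")),
                   roc = stats::setNames(lapply(ms, `[[`, "roc"), classes),
                   labels = classes, positive = NA_character_,
                   predicted = predicted, scores = scores)
  }
  structure(report, class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("leave-one-out SVM over %d samples, classes: %s\n",
              length(x$predicted), paste(x$labels, collapse = ", ")))
  cat(sprintf("  accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f%s\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc,
              if (length(x$labels) > 2L) " (macro one-vs-rest)" else ""))
  invisible(x)
}

#' @export
plot.classification_report <- function(x, ...) {
  rocs <- if (is.matrix(x$roc)) list(x$roc) else x$roc
  graphics::plot(0:1, 0:1, type = "l", lty = 3, col = "grey",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = "ROC", ...)
  for (k in seq_along(rocs))
    graphics::lines(rocs[[k]][, "fpr"], rocs[[k]][, "tpr"], col = k + 1)
  if (!is.matrix(x$roc))
    graphics::legend("bottomright", legend = names(rocs),
                     col = seq_along(rocs) + 1, lty = 1, bty = "n")
  invisible(x)
}

#' Rank-statistic AUC (concordance) from decision scores
#'
#' The probability that a randomly chosen positive sample scores higher
#' than a randomly chosen negative one, with ties counted half.  Provided
#' as an independent check of ROC-derived AUC values.
#'
#' @param scores numeric decision scores (larger favours the positive
#'   class).
#' @param truth logical vector, `TRUE` for positives.
#' @return Scalar AUC.
#' @export
auc_rank <- function(scores, truth) {
  r <- rank(scores)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("need both classes")
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
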