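#' Confusion matrix from truth and prediction
#'
#' @param truth true class labels.
#' @param pred predicted class labels.
#' @param classes class order (default: sorted union).
#' @return integer matrix, rows = truth, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) stop("truth/pred length mismatch")
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  tab <- table(factor(truth, levels = classes),
               factor(pred, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' For two classes the first class is treated as positive:
#' `ACC = (TP+TN)/(TP+TN+FP+FN) * 100`, `SEN = TP/(TP+FN) * 100`,
#' `SPE = TN/(TN+FP) * 100`. For more classes, accuracy is
#' `trace/total * 100` and sensitivity/specificity are macro averages of the
#' one-vs-rest values; a class absent from the test set has undefined
#' sensitivity and is excluded from the macro average with a warning.
#'
#' @param cm square confusion matrix (rows = truth).
#' @return named numeric vector `c(acc, sen, spe)` in percent.
#' @export
#' @examples
#' confusion_metrics(matrix(c(50, 5, 5, 40), 2, byrow = TRUE,
#'                          dimnames = list(c("a","b"), c("a","b"))))
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  K <- nrow(cm)
  acc <- sum(diag(cm)) / total * 100
  sens <- numeric(K); spes <- numeric(K); has_truth <- rowSums(cm) > 0
  for (k in seq_len(K)) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    sens[k] <- if (tp + fn > 0) tp / (tp + fn) * 100 else NA_real_
    spes[k] <- if (tn + fp > 0) tn / (tn + fp) * 100 else NA_real_
  }
  if (K == 2L) {
    sen <- sens[1L]; spe <- spes[1L]
  } else {
    if (any(!has_truth)) {
      warning("class(es) absent from the test set excluded from macro sensitivity: ",
              paste(rownames(cm)[!has_truth], collapse = ", "))
    }
    sen <- mean(sens[has_truth])
    spe <- mean(spes, na.rm = TRUE)
  }
  c(acc = acc, sen = sen, spe = spe)
}

#' Stratified fold assignment
#'
#' Shuffles each class independently and deals its members over the k folds,
#' so per-class fold counts differ by at most one and the folds partition
#' the data.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    stop("class(es) smaller than k = ", k, ": ",
         paste(names(counts)[counts < k], collapse = ", "))
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Repeated stratified k-fold cross-validation
#'
#' Each repeat draws fresh stratified folds from a substream of `seed`; each
#' fold trains on the remaining k-1 folds and is evaluated on the held-out
#' fold. Optionally a per-fold feature selector is applied to the training
#' fold only (leakage-free screening).
#'
#' @param fm a labeled [feature_matrix()].
#' @param spec a [classifier_spec()].
#' @param k folds (default 5).
#' @param repeats repeated runs (default 10).
#' @param seed root seed.
#' @param selector `NULL`, or a function `(x, labels) -> logical mask` fit on
#'   the training fold and applied to both folds.
#' @return object of class `cv_report`: per-repeat, per-fold confusion
#'   matrices and metrics, plus aggregate mean `acc`, `sen`, `spe` (percent).
#' @export
cross_validate <- function(fm, spec, k = 5L, repeats = 10L, seed = 1L,
                           selector = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(spec, "classifier_spec"))
  labels <- fm$labels
  if (anyNA(labels)) stop("feature matrix has unlabeled rows")
  classes <- sort(unique(labels))
  confusions <- vector("list", repeats)
  metrics <- array(NA_real_, dim = c(repeats, k, 3L),
                   dimnames = list(NULL, NULL, c("acc", "sen", "spe")))
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(labels, k, seed = child_seed(seed, r))
    confusions[[r]] <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- folds != f
      x_tr <- fm$x[tr, , drop = FALSE]; y_tr <- labels[tr]
      x_te <- fm$x[!tr, , drop = FALSE]; y_te <- labels[!tr]
      if (!is.null(selector)) {
        mask <- selector(x_tr, y_tr)
        if (!any(mask)) mask[seq_along(mask)] <- TRUE  # keep all if none pass
        x_tr <- x_tr[, mask, drop = FALSE]
        x_te <- x_te[, mask, drop = FALSE]
      }
      model <- fit_classifier(spec, x_tr, y_tr,
                              seed = child_seed(seed, r * 1000L + f))
      pred <- predict(model, x_te)
      cm <- confusion_matrix(y_te, pred, classes = classes)
      confusions[[r]][[f]] <- cm
      metrics[r, f, ] <- confusion_metrics(cm)
    }
  }
  structure(list(classifier = spec$id, k = as.integer(k),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 classes = classes,
                 confusions = confusions,
                 fold_metrics = metrics,
                 acc = mean(metrics[, , "acc"]),
                 sen = mean(metrics[, , "sen"]),
                 spe = mean(metrics[, , "spe"])),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: %d-fold x %d repeats\n", x$classifier,
              x$k, x$repeats))
  cat(sprintf("  mean ACC %.2f%%  SEN %.2f%%  SPE %.2f%%\n",
              x$acc, x$sen, x$spe))
  invisible(x)
}
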