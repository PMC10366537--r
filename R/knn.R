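# Distance-matrix k-nearest-neighbours supporting the preset distance
# variants (Euclidean, cosine, Minkowski p=3) and inverse-squared-distance
# vote weighting.

knn_distance <- function(train, test, metric) {
  if (metric == "euclidean") {
    d2 <- outer(rowSums(test^2), rowSums(train^2), "+") -
      2 * tcrossprod(test, train)
    sqrt(pmax(d2, 0))
  } else if (metric == "cosine") {
    tn <- sqrt(rowSums(test^2)); rn <- sqrt(rowSums(train^2))
    tn[tn == 0] <- 1; rn[rn == 0] <- 1
    1 - tcrossprod(test / tn, train / rn)
  } else if (metric == "minkowski3") {
    out <- matrix(0, nrow(test), nrow(train))
    for (i in seq_len(nrow(test))) {
      out[i, ] <- (colSums(abs(t(train) - test[i, ])^3))^(1 / 3)
    }
    out
  } else {
    stop("unknown metric: ", metric)
  }
}

#' Fit (memorize) a k-nearest-neighbours classifier
#'
#' @param x training matrix (samples x features).
#' @param y training labels.
#' @param k neighbourhood size (capped at the training-set size).
#' @param metric `"euclidean"`, `"cosine"` or `"minkowski3"`.
#' @param weighted if TRUE, votes are weighted by inverse squared distance.
#' @return object of class `mi_knn`.
#' @export
knn_fit <- function(x, y, k = 1L, metric = "euclidean", weighted = FALSE) {
  x <- as.matrix(x)
  y <- as.character(y)
  structure(list(x = x, y = y, classes = sort(unique(y)),
                 k = min(as.integer(k), nrow(x)),
                 metric = metric, weighted = weighted),
            class = "mi_knn")
}

#' Predict from a k-nearest-neighbours classifier
#'
#' Majority (or distance-weighted) vote among the k nearest training
#' samples; vote ties break toward the lowest class index, distance ties
#' toward the earlier training sample.
#'
#' @param object an `mi_knn` model.
#' @param x test matrix.
#' @return character vector of predicted labels.
#' @export
knn_predict <- function(object, x) {
  x <- as.matrix(x)
  D <- knn_distance(object$x, x, object$metric)
  K <- object$k
  classes <- object$classes
  out <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    ord <- order(D[i, ])[seq_len(K)]
    votes <- numeric(length(classes))
    names(votes) <- classes
    if (object$weighted) {
      w <- 1 / pmax(D[i, ord]^2, 1e-12)
    } else {
      w <- rep(1, K)
    }
    for (j in seq_len(K)) {
      votes[object$y[ord[j]]] <- votes[object$y[ord[j]]] + w[j]
    }
    out[i] <- classes[which.max(votes)]
  }
  out
}
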