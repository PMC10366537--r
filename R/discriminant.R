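# Regularized linear discriminant analysis: Gaussian classes with a shared
# pooled covariance, stabilized by diagonal loading so it remains defined
# when the feature count exceeds the sample count (the regime of the full
# 1,364-feature matrix). Base learner of the random-subspace ensemble.

#' Fit a regularized linear discriminant
#'
#' Pooled within-class covariance with diagonal loading
#' `S + reg * tr(S)/p * I`; class posteriors follow the usual Gaussian
#' linear discriminant scores with empirical class priors.
#'
#' @param x numeric matrix (samples x features).
#' @param y class labels (character/factor), every class with >= 2 samples.
#' @param reg relative diagonal loading (default 1e-3).
#' @return object of class `reg_lda`.
#' @export
reg_lda_fit <- function(x, y, reg = 1e-3) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  counts <- table(factor(y, levels = classes))
  if (any(counts < 2L)) {
    stop("class(es) with fewer than 2 training samples: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  n <- nrow(x); p <- ncol(x); K <- length(classes)
  means <- matrix(0, K, p)
  S <- matrix(0, p, p)
  for (k in seq_len(K)) {
    xi <- x[y == classes[k], , drop = FALSE]
    mu <- colMeans(xi)
    means[k, ] <- mu
    cx <- sweep(xi, 2L, mu)
    S <- S + crossprod(cx)
  }
  S <- S / max(n - K, 1L)
  lambda <- reg * max(mean(diag(S)), .Machine$double.eps) + 1e-12
  S_reg <- S + diag(lambda, p)
  ch <- chol(S_reg)
  # discriminant linear coefficients: Sigma^{-1} mu_k
  W <- backsolve(ch, forwardsolve(t(ch), t(means)))
  consts <- -0.5 * colSums(t(means) * W) + log(as.numeric(counts) / n)
  structure(list(classes = classes, W = W, consts = consts,
                 means = means, lambda = lambda),
            class = "reg_lda")
}

#' Predict from a regularized linear discriminant
#'
#' @param object a `reg_lda` model.
#' @param x numeric matrix (samples x features).
#' @return list with `class` (character) and `posterior` (samples x classes
#'   matrix). Posterior ties break toward the lowest class index.
#' @export
reg_lda_predict <- function(object, x) {
  x <- as.matrix(x)
  scores <- x %*% object$W + matrix(object$consts, nrow(x),
                                    length(object$consts), byrow = TRUE)
  # softmax with overflow guard
  scores <- scores - apply(scores, 1L, max)
  post <- exp(scores)
  post <- post / rowSums(post)
  colnames(post) <- object$classes
  cls <- object$classes[apply(post, 1L, which.max)]
  list(class = cls, posterior = post)
}

#' Fit a random-subspace discriminant ensemble
#'
#' Draws `n_learners` random feature subsets of size `subspace_dim` (sampled
#' without replacement within each subset) and fits a regularized linear
#' discriminant on each. Prediction averages class posteriors across
#' learners and takes the argmax, ties breaking toward the lowest class
#' index. Reproducible given `seed`.
#'
#' @param x numeric matrix (samples x features).
#' @param y class labels; every class needs >= 2 samples.
#' @param n_learners ensemble size (default 30).
#' @param subspace_dim features per learner (default `ceiling(p/2)`).
#' @param seed integer seed for the subset draws.
#' @param reg diagonal-loading strength passed to [reg_lda_fit()].
#' @return object of class `subspace_discriminant`.
#' @export
subspace_discriminant_fit <- function(x, y, n_learners = 30L,
                                      subspace_dim = NULL, seed = 1L,
                                      reg = 1e-3) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (is.null(subspace_dim)) subspace_dim <- ceiling(p / 2)
  subspace_dim <- as.integer(subspace_dim)
  n_learners <- as.integer(n_learners)
  if (n_learners < 1L) stop("n_learners must be >= 1")
  if (subspace_dim < 1L || subspace_dim > p) {
    stop("subspace_dim must lie in [1, feature count]")
  }
  subsets <- with_seed(seed, {
    lapply(seq_len(n_learners), function(i) sort(sample.int(p, subspace_dim)))
  })
  learners <- lapply(subsets, function(js) {
    reg_lda_fit(x[, js, drop = FALSE], y, reg = reg)
  })
  structure(list(learners = learners, subsets = subsets,
                 classes = learners[[1L]]$classes,
                 n_learners = n_learners, subspace_dim = subspace_dim,
                 seed = as.integer(seed)),
            class = "subspace_discriminant")
}

#' Predict from a random-subspace discriminant ensemble
#'
#' @param object a `subspace_discriminant` model.
#' @param x numeric matrix (samples x features, full feature space used at
#'   fit time).
#' @return list with `class` and the averaged `posterior` matrix.
#' @export
subspace_discriminant_predict <- function(object, x) {
  x <- as.matrix(x)
  post <- matrix(0, nrow(x), length(object$classes))
  for (i in seq_along(object$learners)) {
    js <- object$subsets[[i]]
    post <- post + reg_lda_predict(object$learners[[i]],
                                   x[, js, drop = FALSE])$posterior
  }
  post <- post / length(object$learners)
  colnames(post) <- object$classes
  cls <- object$classes[apply(post, 1L, which.max)]
  list(class = cls, posterior = post)
}

# internal: per-class diagonal Gaussian classifier; fallback when a full
# quadratic discriminant is singular
diag_gaussian_fit <- function(x, y) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  stats_by <- lapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    v <- apply(xi, 2L, stats::var)
    vpos <- v[is.finite(v) & v > 0]
    fill <- if (length(vpos)) mean(vpos) else 1e-12
    v[!is.finite(v) | v <= 0] <- fill
    list(mu = colMeans(xi), var = v, logprior = log(nrow(xi) / nrow(x)))
  })
  structure(list(classes = classes, stats = stats_by),
            class = "diag_gaussian")
}

diag_gaussian_predict <- function(object, x) {
  x <- as.matrix(x)
  ll <- vapply(object$stats, function(s) {
    rowSums(-0.5 * (sweep(x, 2L, s$mu)^2) / matrix(s$var, nrow(x),
                                                   ncol(x), byrow = TRUE) -
              0.5 * matrix(log(2 * pi * s$var), nrow(x), ncol(x),
                           byrow = TRUE)) + s$logprior
  }, numeric(nrow(x)))
  ll <- matrix(ll, nrow = nrow(x))
  object$classes[apply(ll, 1L, which.max)]
}
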