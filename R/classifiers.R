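# Classifier families and presets. The preset grid mirrors the common
# "classification learner" families: decision trees (fine/medium/coarse),
# linear/quadratic discriminants, Gaussian/kernel Naive Bayes, SVMs with
# linear/polynomial/Gaussian kernels at three kernel scales, six k-NN
# variants, binary logistic regression, and five ensembles (boosted trees,
# bagged trees, random-subspace discriminant, random-subspace k-NN,
# RUSBoosted trees). Preset hyperparameters are stated approximations, not
# bit-matched reproductions of any external tool.

#' Construct a classifier specification
#'
#' @param family one of `"tree"`, `"lda"`, `"qda"`, `"gaussian_nb"`,
#'   `"kernel_nb"`, `"svm"`, `"knn"`, `"logistic"`,
#'   `"ensemble_subspace_discriminant"`, `"ensemble_subspace_knn"`,
#'   `"ensemble_bagged_trees"`, `"ensemble_boosted_trees"`,
#'   `"ensemble_rusboost"`.
#' @param preset family-specific preset: trees and k-NN accept
#'   `"fine"`/`"medium"`/`"coarse"` (k-NN also `"cosine"`, `"cubic"`,
#'   `"weighted"`); SVM accepts `"linear"`, `"quadratic"`, `"cubic"`,
#'   `"fine_gaussian"`, `"medium_gaussian"`, `"coarse_gaussian"`.
#' @param ... hyperparameter overrides (`n_learners`, `subspace_dim`, `k`,
#'   `maxdepth`, `cost`, `reg`, ...).
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(family, preset = NULL, ...) {
  families <- c("tree", "lda", "qda", "gaussian_nb", "kernel_nb", "svm",
                "knn", "logistic", "ensemble_subspace_discriminant",
                "ensemble_subspace_knn", "ensemble_bagged_trees",
                "ensemble_boosted_trees", "ensemble_rusboost")
  family <- match.arg(family, families)
  hyper <- list(...)
  if (is.null(preset)) {
    preset <- switch(family, tree = "medium", knn = "fine", svm = "linear",
                     "default")
  }
  id <- if (preset == "default") family else paste(family, preset, sep = "_")
  structure(list(family = family, preset = preset, hyper = hyper, id = id),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("<classifier_spec> %s\n", x$id))
  invisible(x)
}

# internal: families standardized with train-fold mean/sd (distance- and
# margin-based); trees and discriminants run on raw features
needs_scaling <- function(family) {
  family %in% c("svm", "knn", "logistic", "ensemble_subspace_knn")
}

scale_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}

scale_apply <- function(scaler, x) {
  sweep(sweep(x, 2L, scaler$mu), 2L, scaler$sd, "/")
}

tree_depth_for_splits <- function(splits) {
  max(2L, as.integer(ceiling(log2(splits + 1))))
}

rpart_control_preset <- function(maxdepth) {
  rpart::rpart.control(cp = 0, minsplit = 4L, minbucket = 2L,
                       maxdepth = maxdepth, xval = 0L,
                       maxsurrogate = 0L, maxcompete = 0L)
}

fit_rpart <- function(x, y, maxdepth, weights = NULL) {
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(x)))
  df$.y <- factor(y)
  rpart::rpart(.y ~ ., data = df, method = "class", weights = weights,
               control = rpart_control_preset(maxdepth))
}

predict_rpart <- function(fit, x, type = "class") {
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(x)))
  if (type == "class") {
    as.character(predict(fit, df, type = "class"))
  } else {
    predict(fit, df, type = "prob")
  }
}

# internal: SAMME multi-class AdaBoost over shallow rpart trees; when
# `undersample` is TRUE each learner trains on a weighted random
# undersample balancing classes to the minority count (RUSBoost)
fit_samme <- function(x, y, n_learners, maxdepth, seed,
                      undersample = FALSE) {
  y <- as.character(y)
  classes <- sort(unique(y))
  K <- length(classes)
  n <- nrow(x)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  with_seed(seed, {
    for (m in seq_len(n_learners)) {
      if (undersample) {
        nmin <- min(table(y))
        idx <- unlist(lapply(classes, function(cl) {
          pool <- which(y == cl)
          if (length(pool) <= nmin) pool else
            sample(pool, nmin, prob = w[pool] / sum(w[pool]))
        }), use.names = FALSE)
        fit <- fit_rpart(x[idx, , drop = FALSE], y[idx], maxdepth)
      } else {
        fit <- fit_rpart(x, y, maxdepth, weights = w * n)
      }
      pred <- predict_rpart(fit, x)
      wrong <- pred != y
      err <- sum(w[wrong])
      if (err <= 0) {
        learners[[length(learners) + 1L]] <- fit
        alphas <- c(alphas, log(1e10))
        break
      }
      if (err >= 1 - 1 / K) {
        # learner no better than chance: reset weights and skip it
        w <- rep(1 / n, n)
        next
      }
      alpha <- log((1 - err) / err) + log(K - 1)
      learners[[length(learners) + 1L]] <- fit
      alphas <- c(alphas, alpha)
      w <- w * exp(alpha * wrong)
      w <- w / sum(w)
    }
  })
  if (length(learners) == 0L) {
    # degenerate: fall back to a single unweighted tree
    learners <- list(fit_rpart(x, y, maxdepth))
    alphas <- 1
  }
  list(learners = learners, alphas = alphas, classes = classes)
}

predict_samme <- function(model, x) {
  scores <- matrix(0, nrow(x), length(model$classes))
  colnames(scores) <- model$classes
  for (m in seq_along(model$learners)) {
    pred <- predict_rpart(model$learners[[m]], x)
    for (k in seq_along(model$classes)) {
      scores[, k] <- scores[, k] +
        model$alphas[m] * (pred == model$classes[k])
    }
  }
  model$classes[apply(scores, 1L, which.max)]
}

# internal: kernel Naive Bayes with per-feature Gaussian KDE (Silverman
# bandwidth)
fit_kernel_nb <- function(x, y) {
  y <- as.character(y)
  classes <- sort(unique(y))
  per_class <- lapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    h <- apply(xi, 2L, function(v) {
      n <- length(v)
      s <- min(stats::sd(v), stats::IQR(v) / 1.34)
      if (!is.finite(s) || s <= 0) s <- max(stats::sd(v), 1e-6)
      if (!is.finite(s) || s <= 0) s <- 1e-6
      0.9 * s * n^(-1 / 5)
    })
    list(x = xi, h = h, logprior = log(nrow(xi) / nrow(x)))
  })
  list(classes = classes, per_class = per_class)
}

predict_kernel_nb <- function(model, x) {
  n <- nrow(x)
  ll <- matrix(0, n, length(model$classes))
  for (k in seq_along(model$classes)) {
    pc <- model$per_class[[k]]
    tot <- rep(pc$logprior, n)
    for (j in seq_len(ncol(x))) {
      h <- pc$h[j]
      dens <- vapply(x[, j], function(v) {
        mean(stats::dnorm((v - pc$x[, j]) / h)) / h
      }, numeric(1))
      tot <- tot + log(pmax(dens, 1e-300))
    }
    ll[, k] <- tot
  }
  model$classes[apply(ll, 1L, which.max)]
}

#' Fit a classifier from a specification
#'
#' Distance- and margin-based families (SVM, k-NN, logistic,
#' subspace k-NN) are standardized with the training mean and standard
#' deviation; tree and discriminant families run on raw features. Quadratic
#' discriminants falling on a singular class covariance are refit with a
#' per-class diagonal Gaussian and flagged, never crashed.
#'
#' @param spec a [classifier_spec()].
#' @param x training matrix (samples x features).
#' @param y training labels.
#' @param seed seed for stochastic learners (ensembles).
#' @return object of class `mi_classifier`.
#' @export
fit_classifier <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  p <- ncol(x)
  hy <- spec$hyper
  geth <- function(name, default) if (!is.null(hy[[name]])) hy[[name]] else
    default
  scaler <- NULL
  if (needs_scaling(spec$family)) {
    scaler <- scale_fit(x)
    x <- scale_apply(scaler, x)
  }
  flags <- character(0)
  inner <- switch(spec$family,
    tree = {
      depth <- geth("maxdepth", switch(spec$preset,
        fine = tree_depth_for_splits(100L),
        medium = tree_depth_for_splits(20L),
        coarse = tree_depth_for_splits(4L),
        tree_depth_for_splits(20L)))
      fit_rpart(x, y, depth)
    },
    lda = reg_lda_fit(x, y, reg = geth("reg", 1e-3)),
    qda = {
      fit <- tryCatch(MASS::qda(x, grouping = factor(y)),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        flags <- c(flags, "qda_singular_fallback")
        warning("quadratic discriminant singular; using a diagonal Gaussian fit")
        diag_gaussian_fit(x, y)
      } else fit
    },
    gaussian_nb = e1071::naiveBayes(x = x, y = factor(y)),
    kernel_nb = fit_kernel_nb(x, y),
    svm = {
      ks <- switch(spec$preset,
                   fine_gaussian = sqrt(p) / 4,
                   medium_gaussian = sqrt(p),
                   coarse_gaussian = 4 * sqrt(p),
                   sqrt(p))
      kernel <- switch(spec$preset,
                       linear = "linear",
                       quadratic = "polynomial",
                       cubic = "polynomial",
                       "radial")
      degree <- switch(spec$preset, quadratic = 2L, cubic = 3L, 3L)
      with_seed(seed, e1071::svm(
        x = x, y = factor(y), kernel = kernel, degree = degree,
        gamma = if (kernel == "radial") 1 / (2 * ks^2) else 1 / p,
        coef0 = if (kernel == "polynomial") 1 else 0,
        cost = geth("cost", 1), scale = FALSE))
    },
    knn = {
      k <- geth("k", switch(spec$preset, fine = 1L, medium = 10L,
                            coarse = 100L, 10L))
      metric <- switch(spec$preset, cosine = "cosine",
                       cubic = "minkowski3", "euclidean")
      knn_fit(x, y, k = k, metric = metric,
              weighted = identical(spec$preset, "weighted"))
    },
    logistic = {
      if (length(classes) != 2L) {
        stop("logistic regression is defined for 2 classes only")
      }
      yy <- as.integer(y == classes[2L])
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, x), yy, family = stats::binomial()))
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      list(beta = beta, classes = classes)
    },
    ensemble_subspace_discriminant = subspace_discriminant_fit(
      x, y, n_learners = geth("n_learners", 30L),
      subspace_dim = geth("subspace_dim", ceiling(p / 2)),
      seed = seed, reg = geth("reg", 1e-3)),
    ensemble_subspace_knn = {
      dim <- geth("subspace_dim", ceiling(p / 2))
      nl <- geth("n_learners", 30L)
      subsets <- with_seed(seed, lapply(seq_len(nl), function(i) {
        sort(sample.int(p, dim))
      }))
      learners <- lapply(subsets, function(js) {
        knn_fit(x[, js, drop = FALSE], y, k = geth("k", 1L))
      })
      list(learners = learners, subsets = subsets, classes = classes)
    },
    ensemble_bagged_trees = {
      nl <- geth("n_learners", 30L)
      idxs <- with_seed(seed, lapply(seq_len(nl), function(i) {
        sample.int(nrow(x), nrow(x), replace = TRUE)
      }))
      learners <- lapply(idxs, function(ii) {
        fit_rpart(x[ii, , drop = FALSE], y[ii], maxdepth = 30L)
      })
      list(learners = learners, classes = classes)
    },
    ensemble_boosted_trees = fit_samme(x, y, geth("n_learners", 30L),
                                       geth("maxdepth", 3L), seed),
    ensemble_rusboost = fit_samme(x, y, geth("n_learners", 30L),
                                  geth("maxdepth", 3L), seed,
                                  undersample = TRUE)
  )
  structure(list(spec = spec, scaler = scaler, inner = inner,
                 classes = classes, flags = flags),
            class = "mi_classifier")
}

#' Predict labels from a fitted classifier
#'
#' @param object an `mi_classifier` from [fit_classifier()].
#' @param x test matrix (samples x features, same columns as at fit).
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.mi_classifier <- function(object, x, ...) {
  x <- as.matrix(x)
  if (!is.null(object$scaler)) x <- scale_apply(object$scaler, x)
  fam <- object$spec$family
  inner <- object$inner
  switch(fam,
    tree = predict_rpart(inner, x),
    lda = reg_lda_predict(inner, x)$class,
    qda = {
      if (inherits(inner, "diag_gaussian")) diag_gaussian_predict(inner, x)
      else as.character(predict(inner, x)$class)
    },
    gaussian_nb = as.character(predict(inner, x)),
    kernel_nb = predict_kernel_nb(inner, x),
    svm = as.character(predict(inner, x)),
    knn = knn_predict(inner, x),
    logistic = {
      eta <- as.vector(cbind(1, x) %*% inner$beta)
      ifelse(eta > 0, inner$classes[2L], inner$classes[1L])
    },
    ensemble_subspace_discriminant = subspace_discriminant_predict(inner, x)$class,
    ensemble_subspace_knn = {
      votes <- matrix(0, nrow(x), length(inner$classes))
      colnames(votes) <- inner$classes
      for (i in seq_along(inner$learners)) {
        pred <- knn_predict(inner$learners[[i]],
                            x[, inner$subsets[[i]], drop = FALSE])
        for (k in seq_along(inner$classes)) {
          votes[, k] <- votes[, k] + (pred == inner$classes[k])
        }
      }
      inner$classes[apply(votes, 1L, which.max)]
    },
    ensemble_bagged_trees = {
      prob <- matrix(0, nrow(x), length(inner$classes))
      colnames(prob) <- inner$classes
      for (fit in inner$learners) {
        pr <- predict_rpart(fit, x, type = "prob")
        prob[, colnames(pr)] <- prob[, colnames(pr)] + pr
      }
      inner$classes[apply(prob, 1L, which.max)]
    },
    ensemble_boosted_trees = predict_samme(inner, x),
    ensemble_rusboost = predict_samme(inner, x)
  )
}

#' The full preset grid of classifier specifications
#'
#' Enumerates the full comparison grid: 3 trees, 2 discriminants, 2 Naive
#' Bayes, 6 SVMs, 6 k-NN variants, 5 ensembles, and (for two-class problems)
#' logistic regression.
#'
#' @param binary include the logistic-regression entry (default FALSE).
#' @return named list of [classifier_spec()] objects.
#' @export
classifier_grid <- function(binary = FALSE) {
  specs <- list(
    classifier_spec("tree", "fine"),
    classifier_spec("tree", "medium"),
    classifier_spec("tree", "coarse"),
    classifier_spec("lda"),
    classifier_spec("qda"),
    classifier_spec("gaussian_nb"),
    classifier_spec("kernel_nb"),
    classifier_spec("svm", "linear"),
    classifier_spec("svm", "quadratic"),
    classifier_spec("svm", "cubic"),
    classifier_spec("svm", "fine_gaussian"),
    classifier_spec("svm", "medium_gaussian"),
    classifier_spec("svm", "coarse_gaussian"),
    classifier_spec("knn", "fine"),
    classifier_spec("knn", "medium"),
    classifier_spec("knn", "coarse"),
    classifier_spec("knn", "cosine"),
    classifier_spec("knn", "cubic"),
    classifier_spec("knn", "weighted"),
    classifier_spec("ensemble_boosted_trees"),
    classifier_spec("ensemble_bagged_trees"),
    classifier_spec("ensemble_subspace_discriminant"),
    classifier_spec("ensemble_subspace_knn"),
    classifier_spec("ensemble_rusboost")
  )
  if (binary) {
    specs <- append(specs, list(classifier_spec("logistic")), after = 7L)
  }
  names(specs) <- vapply(specs, function(s) s$id, character(1))
  specs
}
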