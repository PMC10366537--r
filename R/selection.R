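#' Two-sided independent-samples t-test p-value
#'
#' Student's pooled-variance two-sample t-test by default (`welch = TRUE`
#' gives the unequal-variance variant). Degenerate inputs follow the
#' conventions: both groups constant with equal means gives p = 1; constant
#' with different means gives p = 0.
#'
#' @param a,b numeric vectors, each of length >= 2, finite.
#' @param welch use the Welch (unequal variance) test instead of pooled.
#' @return two-sided p-value.
#' @export
#' @examples
#' pvalue_ttest(c(1, 2, 3), c(4, 5, 6))  # ~0.02131
pvalue_ttest <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("both groups need at least 2 observations")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  stats::t.test(a, b, var.equal = !welch)$p.value
}

#' One-way fixed-effects ANOVA p-value
#'
#' F-test for equality of group means. Zero within-group variance follows
#' the conventions: equal means gives p = 1, unequal means p = 0.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2
#'   observations).
#' @return p-value of the F-test.
#' @export
#' @examples
#' pvalue_anova(list(1:3, 4:6, 7:9))  # F = 27 on (2, 6) df
pvalue_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least 2 groups")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least 2 observations")
  vals <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(vals))) stop("non-finite values")
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    mus <- vapply(groups, mean, numeric(1))
    return(if (max(mus) == min(mus)) 1 else 0)
  }
  g <- factor(rep(seq_along(groups), sizes))
  stats::oneway.test(vals ~ g, var.equal = TRUE)$p.value
}

#' Statistical-significance feature screening
#'
#' Computes one p-value per feature column: a two-class label uses the
#' independent t-test, three or more classes the one-way ANOVA. A feature is
#' selected when `p < alpha` (strict; no multiple-testing correction by
#' default, replicating per-feature screening at a fixed significance level;
#' `adjust = "BH"` optionally applies Benjamini-Hochberg as an extension).
#'
#' @param fm a labeled [feature_matrix()] with >= 2 classes, every class
#'   having >= 2 rows.
#' @param alpha significance level (default 0.05).
#' @param welch use the Welch t-test variant in the two-class case.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return object of class `selection_result`: list with `p_values` (named),
#'   `mask` (named logical), `test_used` (`"ttest"` or `"anova"`), `alpha`,
#'   `n_selected`.
#' @export
select_features <- function(fm, alpha = 0.05, welch = FALSE,
                            adjust = c("none", "BH")) {
  stopifnot(inherits(fm, "feature_matrix"))
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  labels <- fm$labels
  if (anyNA(labels)) stop("feature matrix has unlabeled rows")
  classes <- unique(labels)
  if (length(classes) < 2L) stop("need at least 2 classes")
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("class(es) with fewer than 2 rows: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  test_used <- if (length(classes) == 2L) "ttest" else "anova"
  idx <- split(seq_along(labels), labels)[classes]
  p <- vapply(seq_len(ncol(fm$x)), function(j) {
    col <- fm$x[, j]
    if (test_used == "ttest") {
      pvalue_ttest(col[idx[[1L]]], col[idx[[2L]]], welch = welch)
    } else {
      pvalue_anova(lapply(idx, function(i) col[i]))
    }
  }, numeric(1))
  names(p) <- colnames(fm$x)
  p_crit <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  mask <- p_crit < alpha
  structure(list(p_values = p, mask = mask, test_used = test_used,
                 alpha = alpha, adjust = adjust,
                 n_selected = sum(mask)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s at alpha=%g: %d / %d features selected\n",
              x$test_used, x$alpha, x$n_selected, length(x$mask)))
  invisible(x)
}

#' Restrict a feature matrix to selected columns
#'
#' @param fm a [feature_matrix()].
#' @param selection a `selection_result` from [select_features()] or a
#'   logical mask.
#' @return the column-subset [feature_matrix()].
#' @export
apply_selection <- function(fm, selection) {
  stopifnot(inherits(fm, "feature_matrix"))
  mask <- if (inherits(selection, "selection_result")) selection$mask else
    selection
  if (length(mask) != ncol(fm$x)) stop("mask length must equal feature count")
  feature_matrix(fm$x[, mask, drop = FALSE], fm$labels)
}
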