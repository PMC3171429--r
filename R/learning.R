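#' Per-gene two-sample t statistics
#'
#' Pooled-variance two-sample t statistic for every gene, class 0 minus
#' class 1. The pooled SD term gets a 1e-12 additive guard so constant
#' genes yield a finite (near-zero-denominator) statistic instead of
#' NaN. Both classes are drawn with equal covariance in the simulation
#' model, which is why the pooled (rather than Welch) form is used.
#'
#' @param x Numeric matrix, genes x samples.
#' @param labels Integer 0/1 labels, one per sample; both classes need at
#'   least 2 samples.
#' @return Numeric vector of t statistics, one per gene.
#' @examples
#' x <- rbind(c(0, 2, 3, 5))
#' t_statistics(x, c(0, 0, 1, 1))  # -3 / sqrt(2)
#' @export
t_statistics <- function(x, labels) {
  stopifnot(is.matrix(x), length(labels) == ncol(x),
            all(labels %in% c(0L, 1L)))
  n0 <- sum(labels == 0L)
  n1 <- sum(labels == 1L)
  if (n0 < 2L || n1 < 2L)
    stop("both classes need at least 2 samples", call. = FALSE)
  x0 <- x[, labels == 0L, drop = FALSE]
  x1 <- x[, labels == 1L, drop = FALSE]
  m0 <- rowMeans(x0)
  m1 <- rowMeans(x1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1L)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  sp2 <- ((n0 - 1L) * v0 + (n1 - 1L) * v1) / (n0 + n1 - 2L)
  (m0 - m1) / (sqrt(sp2 * (1 / n0 + 1 / n1)) + 1e-12)
}

#' t-test filter feature selection
#'
#' Returns the `n_features` genes with the largest absolute t statistic,
#' ordered by decreasing `|t|`, ties broken towards the lower gene index.
#'
#' @inheritParams t_statistics
#' @param n_features Number of genes to keep, between 1 and `nrow(x)`.
#' @return Integer vector of gene indices with the selection scores in
#'   `attr(, "scores")`.
#' @export
select_top_t <- function(x, labels, n_features) {
  if (n_features < 1L || n_features > nrow(x))
    stop("n_features must lie in [1, n_genes]", call. = FALSE)
  t <- t_statistics(x, labels)
  o <- order(-abs(t), seq_along(t))[seq_len(n_features)]
  structure(o, scores = t[o])
}

#' Train a classification rule on selected features
#'
#' Three rules, all deterministic functions of a complete feature vector:
#'
#' * `lda` — pooled-covariance linear discriminant with equal priors.
#'   The pooled covariance diagonal gets a ridge of
#'   `1e-6 * trace / D`, since feature counts approaching the sample
#'   count make it near-singular. A point exactly on the boundary is
#'   assigned class 0.
#' * `3nn` — 3-nearest-neighbour with Euclidean distance (vote ties are
#'   impossible with two classes and k = 3).
#' * `svm` — linear soft-margin support vector machine with cost fixed
#'   at 1 (via \pkg{e1071}).
#'
#' For the linear rules, the fitted decision function is stored as a
#' weight vector and offset (`label 1` iff `w'x + b > 0`), which also
#' gives the closed-form bolstered error.
#'
#' @inheritParams t_statistics
#' @param features Integer vector of gene row indices to use, in order.
#' @param rule `"lda"`, `"3nn"` or `"svm"`.
#' @param reference Optional list carried along for test-point
#'   imputation (the measured training matrix, its mask, and the
#'   imputation config): once imputation of a new sample depends on the
#'   training data, it is part of the classification rule.
#' @return An `mv_classifier` object.
#' @export
train_classifier <- function(x, labels, features, rule = c("lda", "3nn", "svm"),
                             reference = NULL) {
  rule <- match.arg(rule)
  stopifnot(all(features >= 1L), all(features <= nrow(x)))
  if (min(table(factor(labels, levels = c(0L, 1L)))) < 2L)
    stop("both classes need at least 2 samples", call. = FALSE)
  X <- t(x[features, , drop = FALSE])   # samples x D
  D <- ncol(X)
  par <- switch(rule,
    lda = {
      m0 <- colMeans(X[labels == 0L, , drop = FALSE])
      m1 <- colMeans(X[labels == 1L, , drop = FALSE])
      S <- (crossprod(sweep(X[labels == 0L, , drop = FALSE], 2L, m0)) +
              crossprod(sweep(X[labels == 1L, , drop = FALSE], 2L, m1))) /
        (nrow(X) - 2L)
      diag(S) <- diag(S) + 1e-6 * sum(diag(S)) / D
      w <- tryCatch(solve(S, m1 - m0),
                    error = function(e) stop("pooled covariance singular even after ridge",
                                             call. = FALSE))
      list(w = as.numeric(w), b = -sum(w * (m0 + m1)) / 2)
    },
    `3nn` = list(X = X, y = labels),
    svm = {
      fit <- e1071::svm(X, factor(labels, levels = c(0L, 1L)),
                        kernel = "linear", cost = 1, scale = FALSE)
      wsv <- as.numeric(t(fit$coefs) %*% fit$SV)
      # e1071's decision value is t(coefs) K(SV, x) - rho, positive for
      # the class named first in the decision-value column (which
      # follows order of appearance in the data, not factor levels).
      # Normalise so that w'x + b > 0 means class 1.
      dv <- predict(fit, X[1, , drop = FALSE], decision.values = TRUE)
      pos_class <- strsplit(colnames(attr(dv, "decision.values")), "/")[[1]][1]
      if (pos_class == "1") list(w = wsv, b = -fit$rho)
      else list(w = -wsv, b = fit$rho)
    })
  structure(list(rule = rule, features = as.integer(features),
                 parameters = par, n_genes = nrow(x),
                 reference = reference),
            class = "mv_classifier")
}

#' @export
print.mv_classifier <- function(x, ...) {
  cat(sprintf("mv_classifier: rule %s on %d feature(s)\n",
              x$rule, length(x$features)))
  invisible(x)
}

#' Predict class labels
#'
#' @param object An `mv_classifier`.
#' @param newdata A complete feature matrix (rows = samples) whose
#'   columns are either exactly the classifier's features, or all genes
#'   (then the feature columns are extracted); a single vector is also
#'   accepted.
#' @param ... Unused.
#' @return Integer vector of 0/1 labels.
#' @export
predict.mv_classifier <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  D <- length(object$features)
  if (ncol(newdata) == object$n_genes && object$n_genes != D) {
    newdata <- newdata[, object$features, drop = FALSE]
  } else if (ncol(newdata) != D) {
    stop("newdata must have ", D, " feature columns or ", object$n_genes,
         " gene columns", call. = FALSE)
  }
  p <- object$parameters
  switch(object$rule,
    lda = ,
    svm = as.integer(newdata %*% p$w + p$b > 0),
    `3nn` = as.integer(as.character(
      class::knn(p$X, newdata, factor(p$y, levels = c(0L, 1L)), k = 3L))))
}

#' Tidy and glance methods
#'
#' `tidy()` on a classifier lists the selected features (and linear
#' weights where the rule has them); `glance()` on a BPCA fit reports the
#' model summary.
#'
#' @param x An `mv_classifier` or `bpca_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mv_classifier
#' @export
tidy.mv_classifier <- function(x, ...) {
  out <- tibble::tibble(feature = x$features)
  if (x$rule %in% c("lda", "svm")) out$weight <- x$parameters$w
  out
}
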