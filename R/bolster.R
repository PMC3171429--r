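#' Bolstered resubstitution error
#'
#' Resubstitution error smoothed by a spherical Gaussian kernel centred
#' at every training point, which removes most of the optimistic bias of
#' plain resubstitution at small sample sizes. The kernel SD for a class
#' is chosen so that the kernel's median radial distance equals the
#' class's mean nearest-neighbour distance: with D features the radial
#' distance of a D-dimensional spherical Gaussian is sigma times a chi
#' variate with D degrees of freedom, so
#' `sigma_c = mean_NN_dist_c / sqrt(qchisq(0.5, D))`.
#'
#' For linear rules (LDA, linear SVM) the kernel mass on the wrong side
#' of the hyperplane is a Gaussian tail probability and the estimate is
#' computed in closed form. For 3NN it is estimated with `mc_points`
#' Monte-Carlo draws per training point under a local, restorable seed,
#' so the estimate is deterministic given `seed`.
#'
#' As `sigma_scale` tends to 0 the estimate reduces exactly to
#' resubstitution error.
#'
#' @inheritParams train_classifier
#' @param mc_points Monte-Carlo draws per training point (3NN only).
#' @param seed Seed for the 3NN Monte-Carlo draws.
#' @param sigma_scale Multiplier on the kernel SDs (1 = standard
#'   bolstering, 0 = plain resubstitution).
#' @param classifier Optionally, an already-trained `mv_classifier` on
#'   the same features (skips refitting).
#' @return Error estimate in \[0, 1\].
#' @export
bolstered_error <- function(x, labels, features, rule = c("lda", "3nn", "svm"),
                            mc_points = 100L, seed = 1L, sigma_scale = 1,
                            classifier = NULL) {
  rule <- match.arg(rule)
  if (is.null(classifier)) classifier <- train_classifier(x, labels, features, rule)
  X <- t(x[features, , drop = FALSE])
  D <- ncol(X)
  n <- nrow(X)
  sig <- numeric(n)
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) {
      sig[idx] <- 0
      next
    }
    dm <- as.matrix(dist(X[idx, , drop = FALSE]))
    diag(dm) <- Inf
    mean_nn <- mean(apply(dm, 1L, min))
    sig[idx] <- sigma_scale * mean_nn / sqrt(qchisq(0.5, D))
  }

  if (rule %in% c("lda", "svm")) {
    p <- classifier$parameters
    wn <- sqrt(sum(p$w^2))
    f <- as.numeric(X %*% p$w + p$b)
    margin <- ifelse(labels == 1L, f, -f)   # signed distance to correct side
    per_point <- ifelse(sig > 0 & wn > 0,
                        pnorm(-margin / (sig * wn + (wn == 0))),
                        as.numeric(ifelse(labels == 1L, f <= 0, f > 0)))
    return(mean(per_point))
  }

  # 3NN: Monte-Carlo kernel mass, under a local RNG state.
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  errs <- numeric(n)
  for (i in seq_len(n)) {
    if (sig[i] == 0) {
      pred <- predict(classifier, X[i, , drop = FALSE])
      errs[i] <- as.numeric(pred != labels[i])
    } else {
      draws <- matrix(rnorm(mc_points * D, sd = sig[i]), mc_points, D,
                      byrow = TRUE) + rep(X[i, ], each = mc_points)
      pred <- predict(classifier, draws)
      errs[i] <- mean(pred != labels[i])
    }
  }
  mean(errs)
}
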