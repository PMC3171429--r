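#' Bayesian principal component analysis imputation
#'
#' Fits a probabilistic PCA model to an incomplete expression matrix and
#' fills missing entries with their posterior means. Gene rows are the
#' data points and the sample dimension is modelled:
#' \eqn{y_i = W z_i + \mu + \epsilon_i}, where \eqn{y_i} is gene *i*'s
#' expression profile across samples, \eqn{z_i \sim N(0, I_q)} its factor
#' scores, \eqn{\epsilon_i \sim N(0, \sigma^2 I)}, and the loadings `W`
#' have `q = n_samples - 1` columns. Each loading column carries an
#' automatic relevance determination (ARD) precision \eqn{\alpha_k};
#' redundant factors are driven to zero loading norm during fitting, so
#' the effective model rank is chosen automatically and the method needs
#' no tuning parameter.
#'
#' Fitting alternates (a) an expectation step — posterior factor scores
#' for every gene given its observed samples and posterior-mean fills of
#' its missing entries — with (b) parameter updates — loadings under the
#' ARD ridge \eqn{\sigma^2 \mathrm{diag}(\alpha)}, mean, residual
#' variance, and \eqn{\alpha_k = d / \lVert w_k \rVert^2}. Iteration
#' stops when the root-mean-square change of the imputed entries falls
#' below `bpca_tol`, or at `bpca_max_iter` (with a warning; the last
#' iterate is returned). Initialisation is the deterministic SVD of the
#' row-average-filled matrix, so every fit is reproducible without a
#' seed. The iteration loop is compiled (RcppArmadillo).
#'
#' A factor is counted as *effective* when its loading norm satisfies
#' \eqn{\lVert w_k \rVert^2 \ge 10^{-2} \max_j \lVert w_j \rVert^2}
#' (equivalently, its ARD precision is within a factor 100 of the
#' smallest); the rest are considered suppressed.
#'
#' @param x Numeric expression matrix (genes x samples), >= 3 samples.
#' @param mask Logical mask, `TRUE` = missing; no gene fully missing.
#' @param config An [impute_config()]; only the `bpca_*` fields are used.
#' @return A list with `completed` (the filled matrix, equal to `x` at
#'   observed cells) and `fit` (a `bpca_fit` object with `W` (samples x
#'   q), `mu`, `sigma2`, `alpha`, per-gene `scores` (q x genes),
#'   `n_iter`, `converged`, `n_effective`).
#' @examples
#' x <- tcrossprod(matrix(rnorm(90), 30, 3), matrix(rnorm(24), 8, 3)) +
#'   matrix(rnorm(240, sd = 0.05), 30, 8)
#' mask <- matrix(FALSE, 30, 8); mask[cbind(1:5, c(1, 3, 2, 6, 4))] <- TRUE
#' fit <- impute_bpca(x, mask)
#' fit$fit$n_effective
#' @export
impute_bpca <- function(x, mask, config = impute_config("bpca")) {
  x <- expr_matrix(x)
  check_mask(x, mask)
  if (ncol(x) < 3L) stop("BPCA needs at least 3 samples", call. = FALSE)
  fit <- bpca_core(x, mask, config)
  completed <- x
  completed[mask] <- fit$filled[mask]
  list(completed = completed, fit = fit)
}

# Initialise and run the compiled EM. Optional warm start via `init`
# (list with W, mu, sigma2, filled_guess), used by the augmented-matrix
# refinement of test-point completion.
bpca_core <- function(x, mask, config, init = NULL,
                      max_iter = config$bpca_max_iter) {
  d <- ncol(x)                  # modelled dimension: samples
  n <- nrow(x)                  # data points: genes
  q <- d - 1L
  fill <- if (any(mask)) impute_ravg(x, mask) else x

  if (is.null(init)) {
    mu <- colMeans(fill)
    yc <- sweep(fill, 2L, mu)
    sv <- svd(yc, nu = 0, nv = q)
    W <- sv$v * rep(sv$d[seq_len(q)] / sqrt(n), each = d)
    sigma2 <- max(mean(yc^2) - sum((sv$d[seq_len(q)] / sqrt(n))^2) / d, 1e-6)
  } else {
    mu <- init$mu
    W <- init$W
    sigma2 <- init$sigma2
    q <- ncol(W)
    fill[mask] <- init$filled_guess[mask]
  }
  alpha <- d / (colSums(W^2) + 1e-10)

  res <- bpca_em(fill, matrix(as.integer(mask), n, d), W, mu, sigma2,
                 alpha, config$bpca_tol, as.integer(max_iter))
  if (!res$converged && any(mask))
    warning(sprintf("BPCA did not converge in %d iterations (last rms change %.2e); returning last iterate",
                    res$n_iter, res$last_delta), call. = FALSE)
  norms <- colSums(res$W^2)
  filled <- res$filled
  dimnames(filled) <- dimnames(x)
  structure(list(W = res$W, mu = as.numeric(res$mu), sigma2 = res$sigma2,
                 alpha = as.numeric(res$alpha), scores = res$scores,
                 filled = filled, n_iter = res$n_iter,
                 converged = res$converged,
                 n_effective = sum(norms >= 1e-2 * max(norms))),
            class = "bpca_fit")
}

#' @export
print.bpca_fit <- function(x, ...) {
  cat(sprintf("BPCA fit: %d x %d loadings, %d effective factor(s), sigma^2 = %.3g, %d iteration(s)%s\n",
              nrow(x$W), ncol(x$W), x$n_effective, x$sigma2, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @rdname tidy.mv_classifier
#' @method glance bpca_fit
#' @export
glance.bpca_fit <- function(x, ...) {
  tibble::tibble(n_factors = ncol(x$W), n_effective = x$n_effective,
                 sigma2 = x$sigma2, n_iter = x$n_iter,
                 converged = x$converged)
}

# Complete one new sample against a trained BPCA model. The new sample
# is a new coordinate of the modelled sample space, so its loading row
# and offset are estimated by principal-component regression: regress
# the sample's observed values on the training factor scores of those
# genes (ARD-ridged), then fill each missing gene from its score. With
# bpca_test_refine_iter > 0, warm-started EM iterations on the augmented
# (train + sample) matrix refine the completion.
bpca_complete_sample <- function(fit, train_x, train_mask, x_new, miss_new,
                                 config) {
  o <- which(!miss_new)
  q <- ncol(fit$W)
  S <- t(fit$scores)                       # genes x q
  So <- S[o, , drop = FALSE]
  mu_new <- mean(x_new[o])
  A <- crossprod(So) + fit$sigma2 * diag(fit$alpha, q)
  for (it in 1:2) {
    w_new <- solve(A, as.numeric(crossprod(So, x_new[o] - mu_new)))
    mu_new <- mean(x_new[o] - So %*% w_new)
  }
  out <- x_new
  out[miss_new] <- S[miss_new, , drop = FALSE] %*% w_new + mu_new

  if (config$bpca_test_refine_iter > 0L && any(miss_new)) {
    aug_x <- cbind(train_x, new = out)
    aug_mask <- cbind(train_mask, new = miss_new)
    init <- list(mu = c(fit$mu, mu_new),
                 W = rbind(fit$W, as.numeric(w_new)),
                 sigma2 = fit$sigma2,
                 filled_guess = cbind(fit$filled, new = out))
    refined <- bpca_core(aug_x, aug_mask, config, init = init,
                         max_iter = config$bpca_test_refine_iter)
    out[miss_new] <- refined$filled[miss_new, ncol(aug_x)]
  }
  out
}
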