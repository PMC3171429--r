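#' Imputation configuration
#'
#' @param method One of `"ravg"`, `"knn"`, `"lls_l2"`, `"lls_pc"`, `"ls"`,
#'   `"bpca"`.
#' @param k_neighbors Number of neighbour genes for KNN imputation
#'   (default 10; values in 10-20 are the usual recommendation).
#' @param k_candidates Candidate-set size for LLS and LS (default 20).
#'   The LLS regression has one coefficient per candidate, so the
#'   candidate count must stay well below the number of observed
#'   positions (about the sample count) for the local least-squares
#'   problem to remain overdetermined; near-saturated fits interpolate
#'   measurement noise and extrapolate wildly at the missing positions.
#'   With the study's 60-sample geometry, 20 keeps a comfortable margin
#'   even at 25% missingness and matches the 10-20 neighbour range
#'   recommended for candidate-based imputation.
#' @param distance_epsilon Small constant added to every distance before
#'   taking reciprocal KNN weights, so exact duplicates do not divide by
#'   zero while still dominating the weighting. Default 1e-6.
#' @param bpca_max_iter,bpca_tol BPCA stopping rule: iterate until the
#'   root-mean-square change of the imputed entries drops below
#'   `bpca_tol` or `bpca_max_iter` iterations. Defaults 200 and 1e-4.
#' @param bpca_test_refine_iter When completing a single new sample
#'   against a trained BPCA model, number of warm-started refinement
#'   iterations run on the augmented matrix. Default 0: the new sample is
#'   completed by conditioning on the trained model (see
#'   [impute_test_point()]).
#' @return An `impute_config` list.
#' @export
impute_config <- function(method = c("ravg", "knn", "lls_l2", "lls_pc",
                                     "ls", "bpca"),
                          k_neighbors = 10L, k_candidates = 20L,
                          distance_epsilon = 1e-6,
                          bpca_max_iter = 200L, bpca_tol = 1e-4,
                          bpca_test_refine_iter = 0L) {
  method <- match.arg(method)
  stopifnot(k_neighbors >= 1L, k_candidates >= 1L, distance_epsilon > 0,
            bpca_max_iter >= 1L, bpca_tol > 0, bpca_test_refine_iter >= 0L)
  structure(list(method = method, k_neighbors = as.integer(k_neighbors),
                 k_candidates = as.integer(k_candidates),
                 distance_epsilon = distance_epsilon,
                 bpca_max_iter = as.integer(bpca_max_iter),
                 bpca_tol = bpca_tol,
                 bpca_test_refine_iter = as.integer(bpca_test_refine_iter)),
            class = "impute_config")
}

#' Impute missing values in an expression matrix
#'
#' Front end to the six imputation algorithms. The returned matrix is
#' complete and equals the input at every unmasked cell; only masked
#' cells are estimated.
#'
#' * `ravg` — row average: a gene's missing values are replaced by the
#'   mean of its observed values.
#' * `knn` — weighted average of the K most similar genes (Euclidean
#'   distance over jointly observed positions), weights proportional to
#'   reciprocal distance: a convex combination.
#' * `lls_l2`, `lls_pc` — local least squares: unconstrained linear
#'   regression of the target gene on its `k_candidates` most similar
#'   genes (Euclidean distance resp. absolute Pearson correlation),
#'   solved by pseudoinverse (minimum-norm least squares).
#' * `ls` — least-squares imputation: convex combination of single-gene
#'   regression estimates, weighted by an increasing function of the
#'   squared correlation.
#' * `bpca` — Bayesian PCA with automatic relevance determination, see
#'   [impute_bpca()].
#'
#' @param x Numeric expression matrix (genes x samples).
#' @param mask Logical mask, `TRUE` = missing; no gene may be fully
#'   missing.
#' @param method Method token, see [impute_config()]; ignored when
#'   `config` is supplied.
#' @param ... Options passed to [impute_config()].
#' @param config An [impute_config()] object.
#' @param targets Optional integer vector of gene rows to impute
#'   (advanced; other genes' missing cells are left at their input
#'   values). Per-target computations of ravg/knn/lls/ls are independent,
#'   so restricting targets returns exactly the values a full run would.
#'   Ignored by BPCA, which completes the whole matrix jointly.
#' @return Complete numeric matrix of the same shape and dimnames.
#' @examples
#' x <- matrix(rnorm(40), 8, 5)
#' mask <- matrix(FALSE, 8, 5); mask[1, 2] <- TRUE
#' xi <- impute(x, mask, "knn", k_neighbors = 3)
#' all(xi[!mask] == x[!mask])
#' @export
impute <- function(x, mask, method = "ravg", ..., config = NULL,
                   targets = NULL) {
  if (is.null(config)) config <- impute_config(method, ...)
  stopifnot(inherits(config, "impute_config"))
  x <- expr_matrix(x)
  check_mask(x, mask)
  if (nrow(x) < 2L) stop("imputation needs at least 2 genes", call. = FALSE)
  switch(config$method,
    ravg = impute_ravg(x, mask, targets = targets),
    knn = impute_knn(x, mask, config, targets = targets),
    lls_l2 = impute_lls(x, mask, config, metric = "L2", targets = targets),
    lls_pc = impute_lls(x, mask, config, metric = "PC", targets = targets),
    ls = impute_ls(x, mask, config, targets = targets),
    bpca = impute_bpca(x, mask, config)$completed
  )
}

target_rows <- function(mask, targets) {
  rows <- which(rowSums(mask) > 0L)
  if (!is.null(targets)) rows <- intersect(rows, as.integer(targets))
  rows
}

#' @rdname impute
#' @export
impute_ravg <- function(x, mask, targets = NULL) {
  check_mask(x, mask)
  out <- x
  rows <- target_rows(mask, targets)
  if (length(rows) == 0L) return(out)
  means <- rowSums(x[rows, , drop = FALSE] * !mask[rows, , drop = FALSE]) /
    rowSums(!mask[rows, , drop = FALSE])
  for (i in seq_along(rows)) {
    r <- rows[i]
    out[r, mask[r, ]] <- means[i]
  }
  out
}

#' KNN candidate ranking for one target gene
#'
#' Eligible candidates are genes observed at every one of the target's
#' missing positions (so their values can be averaged there directly).
#' Similarity is the scaled Euclidean distance over positions where both
#' target and candidate are observed: sum of squared differences divided
#' by the number of jointly observed positions, square-rooted, so genes
#' with different observation patterns are comparable. Ties are broken
#' towards the lower gene index.
#'
#' @param x,mask Matrix and mask as in [impute()].
#' @param target Integer row index of the target gene.
#' @param K Number of neighbours requested; fewer are returned (with an
#'   informational log message) when fewer genes are eligible.
#' @return A data frame with columns `gene` and `distance`, at most `K`
#'   rows, ordered by increasing distance. Zero rows means no gene is
#'   eligible and the caller should fall back to row-average for this
#'   target.
#' @export
knn_candidates <- function(x, mask, target, K) {
  stopifnot(K >= 1L, target >= 1L, target <= nrow(x))
  tmiss <- which(mask[target, ])
  tobs <- which(!mask[target, ])
  obs <- !mask
  eligible <- which(rowSums(mask[, tmiss, drop = FALSE]) == 0L)
  eligible <- setdiff(eligible, target)
  if (length(eligible) == 0L)
    return(data.frame(gene = integer(0), distance = numeric(0)))
  jobs <- obs[eligible, tobs, drop = FALSE]
  d2 <- (x[eligible, tobs, drop = FALSE] -
           rep(x[target, tobs], each = length(eligible)))^2 * jobs
  n_joint <- rowSums(jobs)
  dist <- ifelse(n_joint > 0, sqrt(rowSums(d2) / pmax(n_joint, 1)), Inf)
  keep <- is.finite(dist)
  eligible <- eligible[keep]
  dist <- dist[keep]
  if (length(eligible) == 0L)
    return(data.frame(gene = integer(0), distance = numeric(0)))
  o <- order(dist, eligible)
  if (length(o) < K)
    mv_log("debug", sprintf("gene %d: only %d eligible KNN candidates (K = %d)",
                            target, length(o), K))
  o <- o[seq_len(min(K, length(o)))]
  data.frame(gene = eligible[o], distance = dist[o])
}

#' @rdname impute
#' @export
impute_knn <- function(x, mask, config = impute_config("knn"),
                       targets = NULL) {
  check_mask(x, mask)
  out <- x
  eps <- config$distance_epsilon
  for (t in target_rows(mask, targets)) {
    cand <- knn_candidates(x, mask, t, config$k_neighbors)
    tmiss <- which(mask[t, ])
    if (nrow(cand) == 0L) {
      mv_log("info", sprintf("gene %d: no eligible KNN candidates, row-average fallback", t))
      out[t, tmiss] <- mean(x[t, !mask[t, ]])
      next
    }
    w <- 1 / (cand$distance + eps)
    w <- w / sum(w)
    out[t, tmiss] <- as.numeric(w %*% x[cand$gene, tmiss, drop = FALSE])
  }
  out
}

# Minimum-norm least-squares solve of  A w = b  via SVD pseudoinverse.
pinv_solve <- function(A, b, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d, 0)
  if (!any(keep)) return(numeric(ncol(A)))
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep])
}

# Rank candidate genes for LLS/LS on the RAVG-pre-filled matrix,
# restricted to the target's observed positions. metric "L2": smallest
# Euclidean distance; "PC": largest |Pearson correlation| (zero-variance
# rows get correlation 0). Ties towards lower gene index.
rank_candidates <- function(filled, tobs, target, k, metric) {
  others <- setdiff(seq_len(nrow(filled)), target)
  b <- filled[target, tobs]
  C <- filled[others, tobs, drop = FALSE]
  if (metric == "L2") {
    score <- rowSums((C - rep(b, each = nrow(C)))^2)
    o <- order(score, others)
  } else {
    n <- length(b)
    r <- numeric(nrow(C))
    if (n >= 2L) {
      rm <- rowMeans(C)
      rv <- rowSums(C^2) / n - rm^2          # population moments: ranking only
      vb <- mean(b^2) - mean(b)^2
      cv <- as.numeric(C %*% b) / n - rm * mean(b)
      ok <- rv > 0 & vb > 0
      r[ok] <- abs(cv[ok] / sqrt(rv[ok] * vb))
    }
    o <- order(-r, others)
  }
  others[o][seq_len(min(k, length(others)))]
}

#' @rdname impute
#' @param metric Candidate similarity for LLS: `"L2"` (Euclidean) or
#'   `"PC"` (absolute Pearson correlation).
#' @export
impute_lls <- function(x, mask, config = impute_config("lls_l2"),
                       metric = c("L2", "PC"), targets = NULL) {
  metric <- match.arg(metric)
  check_mask(x, mask)
  rows <- target_rows(mask, targets)
  out <- x
  if (length(rows) == 0L) return(out)
  filled <- impute_ravg(x, mask)
  for (t in rows) {
    tobs <- which(!mask[t, ])
    tmiss <- which(mask[t, ])
    cand <- rank_candidates(filled, tobs, t, config$k_candidates, metric)
    A <- filled[cand, tobs, drop = FALSE]      # k x n_obs
    w <- pinv_solve(t(A), x[t, tobs])          # n_obs x k system
    out[t, tmiss] <- as.numeric(t(filled[cand, tmiss, drop = FALSE]) %*% w)
  }
  out
}

#' @rdname impute
#' @export
impute_ls <- function(x, mask, config = impute_config("ls"),
                      targets = NULL) {
  check_mask(x, mask)
  rows <- target_rows(mask, targets)
  out <- x
  if (length(rows) == 0L) return(out)
  filled <- impute_ravg(x, mask)
  for (t in rows) {
    tobs <- which(!mask[t, ])
    tmiss <- which(mask[t, ])
    cand <- rank_candidates(filled, tobs, t, config$k_candidates, "PC")
    b <- x[t, tobs]
    vb <- if (length(b) >= 2L) var(b) else 0
    ests <- matrix(0, length(cand), length(tmiss))
    r2 <- numeric(length(cand))
    for (j in seq_along(cand)) {
      cj <- filled[cand[j], tobs]
      v <- if (length(cj) >= 2L) var(cj) else 0
      if (v > 0 && vb > 0) {
        beta <- cov(b, cj) / v
        r2[j] <- cor(b, cj)^2
      } else {
        beta <- 0
      }
      alpha <- mean(b) - beta * mean(cj)
      ests[j, ] <- alpha + beta * filled[cand[j], tmiss]
    }
    w <- (r2 / (1 - r2 + 1e-6))^2
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
    out[t, tmiss] <- as.numeric(w %*% ests)
  }
  out
}
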