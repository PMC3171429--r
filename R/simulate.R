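#' Block-diagonal gene covariance
#'
#' Builds the covariance of the correlated gene-effect term: genes are
#' grouped into consecutive blocks (gene clusters, e.g. pathways); genes
#' within a block share variance `block_sd^2` and pairwise covariance
#' `block_sd^2 * block_corr`; genes in different blocks are uncorrelated.
#' If `block_size` does not divide `n_genes` the final block is smaller.
#'
#' The matrix is positive semidefinite for any `block_corr` in \[0, 1):
#' an m-gene block has eigenvalues `block_sd^2 (1 - corr)` (m - 1 times)
#' and `block_sd^2 (1 + (m - 1) corr)`.
#'
#' @param n_genes,block_size,block_sd,block_corr See [sim_params()].
#' @return An object of class `block_cov`: list with the full `matrix`,
#'   the per-block `sizes`, the gene-to-block `index`, and the parameters.
#' @examples
#' bc <- block_covariance(4, 2, 1, 0.9)
#' bc$matrix
#' @export
block_covariance <- function(n_genes, block_size, block_sd, block_corr) {
  if (n_genes < 1L || block_size < 1L)
    stop("n_genes and block_size must be >= 1", call. = FALSE)
  if (block_sd <= 0) stop("block_sd must be > 0", call. = FALSE)
  if (block_corr < 0 || block_corr >= 1)
    stop("block_corr must lie in [0, 1): the block covariance is only a ",
         "valid correlation model there", call. = FALSE)
  index <- rep(seq_len(ceiling(n_genes / block_size)),
               each = block_size)[seq_len(n_genes)]
  sizes <- tabulate(index)
  mat <- matrix(0, n_genes, n_genes)
  for (b in seq_along(sizes)) {
    idx <- which(index == b)
    mat[idx, idx] <- block_sd^2 * block_corr
  }
  diag(mat) <- block_sd^2
  structure(list(matrix = mat, sizes = sizes, index = index,
                 block_sd = block_sd, block_corr = block_corr),
            class = "block_cov")
}

#' Class fold-change offsets
#'
#' Draws the class-dependent signal component. The first `n_markers`
#' genes are markers (deterministic placement, so markers span the first
#' correlation blocks); each marker gets two fold-change magnitudes drawn
#' from Normal(`mu_fold`, `sd_fold`) — one per class — and a random sign
#' applied oppositely to the two classes, so the expected between-class
#' separation of a marker is `2 * mu_fold` log2 units. Non-marker genes
#' have zero offsets in both classes.
#'
#' @param params A [sim_params()] object. Uses the current RNG state.
#' @return A list of class `fold_changes`: `offset0`, `offset1` (length
#'   `n_genes`), and `markers` (integer indices).
#' @export
sample_fold_changes <- function(params) {
  n <- params$n_genes
  m <- params$n_markers
  offset0 <- numeric(n)
  offset1 <- numeric(n)
  markers <- seq_len(m)
  if (m > 0) {
    s <- sample(c(-1, 1), m, replace = TRUE)
    mag0 <- rnorm(m, params$mu_fold, params$sd_fold)
    mag1 <- rnorm(m, params$mu_fold, params$sd_fold)
    offset0[markers] <- s * mag0
    offset1[markers] <- -s * mag1
  }
  structure(list(offset0 = offset0, offset1 = offset1, markers = markers),
            class = "fold_changes")
}

#' True-signal matrix
#'
#' Each sample column is the class-appropriate fold-change offset vector
#' plus one independent draw from the zero-mean multivariate Gaussian gene
#' effect with the given block covariance. Sampling exploits the block
#' structure: each block is drawn through its Cholesky factor.
#'
#' @param params A [sim_params()] object.
#' @param fc A [sample_fold_changes()] result.
#' @param cov A [block_covariance()] object of dimension `n_genes`.
#' @param labels Integer 0/1 class labels, one per sample.
#' @return Numeric matrix `n_genes` x `length(labels)`.
#' @export
sample_signal <- function(params, fc, cov, labels) {
  stopifnot(inherits(cov, "block_cov"), length(cov$index) == params$n_genes)
  stopifnot(all(labels %in% c(0L, 1L)))
  n_samp <- length(labels)
  effect <- matrix(0, params$n_genes, n_samp)
  for (b in seq_along(cov$sizes)) {
    idx <- which(cov$index == b)
    L <- t(chol(cov$matrix[idx, idx, drop = FALSE]))
    effect[idx, ] <- L %*% matrix(rnorm(length(idx) * n_samp),
                                  length(idx), n_samp)
  }
  offsets <- cbind(fc$offset0, fc$offset1)[, labels + 1L, drop = FALSE]
  expr_matrix(offsets + effect,
              sample_ids = paste0("s", seq_len(n_samp)))
}

#' Heteroscedastic additive noise
#'
#' Per-gene noise SDs are drawn from an exponential distribution with
#' mean `noise_mean`, then entries are independent zero-mean Gaussians
#' with the gene's SD. The exponential SD mixture reproduces the strongly
#' non-homogeneous missing-value distribution of real arrays: a minority
#' of high-noise genes carries most of the low-quality spots.
#'
#' @param params A [sim_params()] object.
#' @param n_samples Number of sample columns to draw.
#' @return A list: `noise` (matrix) and `sigma` (per-gene SDs, kept for
#'   diagnostics).
#' @export
sample_noise <- function(params, n_samples) {
  if (params$noise_mean <= 0) stop("noise_mean must be > 0", call. = FALSE)
  sigma <- rexp(params$n_genes, rate = 1 / params$noise_mean)
  noise <- matrix(rnorm(params$n_genes * n_samples, sd = rep(sigma, n_samples)),
                  params$n_genes, n_samples)
  list(noise = noise, sigma = sigma)
}

#' Quality threshold for missing-value generation
#'
#' Returns the cutoff `t` such that flagging entries with `|noise| > t`
#' as missing yields `round(mv_rate * n * d)` missing entries: `t` is the
#' (k+1)-th largest pooled `|noise|` value (the maximum for `k = 0`), the
#' empirical (1 - mv_rate) quantile up to ties. Training masks additionally
#' use rank thresholding so the requested count is hit exactly; held-out
#' data are masked against this same `t`, so their realised rate
#' fluctuates around the nominal one.
#'
#' @param noise Numeric matrix of noise values.
#' @param mv_rate Target missing fraction in \[0, 1).
#' @return The scalar threshold.
#' @export
quality_threshold <- function(noise, mv_rate) {
  if (mv_rate < 0 || mv_rate >= 1)
    stop("mv_rate must lie in [0, 1)", call. = FALSE)
  a <- sort(abs(noise), decreasing = TRUE)
  k <- round(mv_rate * length(a))
  if (k >= length(a)) stop("mv_rate would mask every entry", call. = FALSE)
  if (k == 0L) a[1L] else a[k + 1L]
}

#' Missing-value mask generation
#'
#' Quality mode marks the entries with the largest `|noise|` as missing —
#' low-quality spots are exactly those with the largest measurement error.
#' With `mv_rate` given, rank thresholding hits `round(mv_rate * n * d)`
#' entries exactly, ties broken towards lower (gene, sample) coordinates;
#' with `threshold` given (held-out partitions reusing a training
#' threshold), entries with `|noise| > threshold` are flagged. Random mode
#' flags a uniform random subset of the same size, reproducing the
#' missing-at-random mechanism of earlier benchmark studies.
#'
#' @param noise Noise matrix (quality mode) or any matrix giving the shape
#'   (random mode).
#' @param mode `"quality"` or `"random"`.
#' @param mv_rate Target missing fraction (required in random mode, and in
#'   quality mode when `threshold` is absent).
#' @param threshold Optional quality cutoff from [quality_threshold()].
#' @return Logical mask matrix; errors if any gene row ends up fully
#'   masked (the pipeline needs observed values in every gene — lower the
#'   MV rate or noise level).
#' @export
generate_mask <- function(noise, mode = c("quality", "random"),
                          mv_rate = NULL, threshold = NULL) {
  mode <- match.arg(mode)
  mask <- matrix(FALSE, nrow(noise), ncol(noise))
  if (mode == "quality" && !is.null(threshold)) {
    mask[abs(noise) > threshold] <- TRUE
  } else {
    if (is.null(mv_rate)) stop("mv_rate required", call. = FALSE)
    k <- round(mv_rate * length(noise))
    if (k >= length(noise)) stop("mv_rate would mask every entry", call. = FALSE)
    if (k > 0) {
      if (mode == "quality") {
        o <- order(-abs(noise), row(noise), col(noise))[seq_len(k)]
      } else {
        o <- sample.int(length(noise), k)
      }
      mask[o] <- TRUE
    }
  }
  full <- which(rowSums(mask) == ncol(mask))
  if (length(full) > 0)
    stop("mask leaves gene(s) with no observed values (rows ",
         paste(head(full), collapse = ", "),
         "); reduce mv_rate or noise_mean", call. = FALSE)
  mask
}

#' Simulate one dataset partition
#'
#' Generates the full bundle for one partition: true signal, noise,
#' measured values (`measured = signal + noise` elementwise), missing-value
#' mask, and balanced class labels. A test partition must reuse the
#' training partition's fold changes, covariance and quality threshold
#' (pass the training dataset as `shared`); its mask is computed from its
#' own noise against that shared threshold, and its own masking never
#' looks at training data.
#'
#' All randomness derives deterministically from `params$seed` and
#' `repetition`, with separate child streams per partition, so the same
#' call is bitwise reproducible.
#'
#' @param params A [sim_params()] object.
#' @param partition `"train"` or `"test"`.
#' @param shared For `partition = "test"`: the training `sim_dataset`
#'   (or a list with `fc`, `cov`, `threshold`).
#' @param repetition Repetition index used in child-seed derivation.
#' @return An object of class `sim_dataset`: list with `signal`, `noise`,
#'   `sigma`, `measured`, `mask`, `labels`, `threshold`, `fc`, `cov`,
#'   `params`, `partition`.
#' @examples
#' p <- sim_params(n_genes = 50, n_markers = 5, n_train = 20, n_test = 10,
#'                 block_size = 10, seed = 7)
#' tr <- simulate_dataset(p, "train")
#' te <- simulate_dataset(p, "test", shared = tr)
#' mean(tr$mask)  # == p$mv_rate exactly
#' @export
simulate_dataset <- function(params, partition = c("train", "test"),
                             shared = NULL, repetition = 1L) {
  partition <- match.arg(partition)
  validate_sim_params(params)
  n_samp <- if (partition == "train") params$n_train else params$n_test
  labels <- rep(c(0L, 1L), each = n_samp %/% 2L)

  if (partition == "train") {
    set.seed(derive_seed(params$seed, repetition, 1L))
    fc <- sample_fold_changes(params)
    cov <- block_covariance(params$n_genes, params$block_size,
                            params$block_sd, params$block_corr)
  } else {
    if (is.null(shared) || is.null(shared$fc) || is.null(shared$cov) ||
        is.null(shared$threshold))
      stop("test partitions must reuse the training partition's fold ",
           "changes, covariance and threshold (pass `shared`)", call. = FALSE)
    fc <- shared$fc
    cov <- shared$cov
  }

  set.seed(derive_seed(params$seed, repetition,
                       if (partition == "train") 2L else 3L))
  signal <- sample_signal(params, fc, cov, labels)
  nz <- sample_noise(params, n_samp)
  measured <- expr_matrix(signal + nz$noise)
  dimnames(measured) <- dimnames(signal)

  if (partition == "train") {
    threshold <- quality_threshold(nz$noise, params$mv_rate)
    mask <- if (params$mask_mode == "quality") {
      generate_mask(nz$noise, "quality", mv_rate = params$mv_rate)
    } else {
      generate_mask(nz$noise, "random", mv_rate = params$mv_rate)
    }
  } else {
    threshold <- shared$threshold
    mask <- if (params$mask_mode == "quality") {
      generate_mask(nz$noise, "quality", threshold = threshold)
    } else {
      generate_mask(nz$noise, "random", mv_rate = params$mv_rate)
    }
  }
  dimnames(mask) <- dimnames(signal)

  structure(list(signal = signal, noise = nz$noise, sigma = nz$sigma,
                 measured = measured, mask = mask, labels = labels,
                 threshold = threshold, fc = fc, cov = cov,
                 params = params, partition = partition),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated %s dataset: %d genes x %d samples, %.1f%% missing (%s masking)\n",
              x$partition, nrow(x$measured), ncol(x$measured),
              100 * mean(x$mask), x$params$mask_mode))
  invisible(x)
}
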