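#' Simulation parameters
#'
#' Bundles every tunable constant of the synthetic-data model: the geometry
#' of the expression matrix, the class fold-change distribution, the
#' block covariance of the correlated gene effect, the heteroscedastic
#' noise level, and the missing-value mechanism.
#'
#' The model generates log2-ratio expression values
#' \eqn{y_{ij} = s_{ij} + e_{ij}}: a true signal (class fold-change offset
#' plus a zero-mean multivariate Gaussian gene effect with block-diagonal
#' covariance) plus additive Gaussian noise whose per-gene standard
#' deviation is drawn from an exponential distribution with mean
#' `noise_mean`. Entries are declared missing either where \eqn{|e_{ij}|}
#' exceeds a quantile threshold (`mask_mode = "quality"`, modelling
#' low-quality spots) or uniformly at random (`mask_mode = "random"`).
#'
#' @param n_genes Total number of genes (rows). Default 500.
#' @param n_markers Number of marker genes carrying a class-dependent
#'   fold-change offset. Default 30. Markers occupy the first `n_markers`
#'   rows, so they span the first few correlation blocks.
#' @param n_train,n_test Training / test sample counts (columns); both are
#'   split evenly between the two classes. Defaults 60 and 200.
#' @param mu_fold Mean of the per-class log2 fold-change magnitude.
#'   Default 0.58, i.e. a 1.5-fold change on the linear scale.
#' @param sd_fold SD of the log2 fold-change magnitude. Default 0.1.
#' @param block_sd Within-block gene-effect SD (log2 units). Default 0.4.
#' @param block_corr Within-block gene-gene correlation, in \[0, 1).
#'   Default 0.5.
#' @param block_size Number of genes per correlation block. Default 25.
#' @param noise_mean Mean of the exponential distribution from which
#'   per-gene noise SDs are drawn (log2 units). Default 0.8.
#' @param mv_rate Fraction of entries to mask, in \[0, 1). Default 0.10.
#' @param mask_mode `"quality"` (noise-magnitude thresholding) or
#'   `"random"` (uniform masking). Default `"quality"`.
#' @param seed Integer root seed; all random streams of a run derive from
#'   it deterministically.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params(n_genes = 100, block_size = 10, seed = 1)
#' p$mv_rate
#' @export
sim_params <- function(n_genes = 500L, n_markers = 30L,
                       n_train = 60L, n_test = 200L,
                       mu_fold = 0.58, sd_fold = 0.1,
                       block_sd = 0.4, block_corr = 0.5, block_size = 25L,
                       noise_mean = 0.8, mv_rate = 0.10,
                       mask_mode = c("quality", "random"),
                       seed = 1L) {
  p <- list(
    n_genes = as.integer(n_genes), n_markers = as.integer(n_markers),
    n_train = as.integer(n_train), n_test = as.integer(n_test),
    mu_fold = as.numeric(mu_fold), sd_fold = as.numeric(sd_fold),
    block_sd = as.numeric(block_sd), block_corr = as.numeric(block_corr),
    block_size = as.integer(block_size),
    noise_mean = as.numeric(noise_mean), mv_rate = as.numeric(mv_rate),
    mask_mode = match.arg(mask_mode), seed = as.integer(seed)
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (p$n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (p$n_markers < 0L || p$n_markers > p$n_genes)
    stop("n_markers must lie in [0, n_genes]", call. = FALSE)
  if (p$n_train < 4L || p$n_train %% 2L != 0L)
    stop("n_train must be an even count >= 4 (balanced classes)", call. = FALSE)
  if (p$n_test < 2L || p$n_test %% 2L != 0L)
    stop("n_test must be an even count >= 2 (balanced classes)", call. = FALSE)
  if (p$sd_fold < 0) stop("sd_fold must be >= 0", call. = FALSE)
  if (p$block_sd <= 0) stop("block_sd must be > 0", call. = FALSE)
  if (p$block_corr < 0 || p$block_corr >= 1)
    stop("block_corr must lie in [0, 1)", call. = FALSE)
  if (p$block_size < 1L) stop("block_size must be >= 1", call. = FALSE)
  if (p$noise_mean <= 0) stop("noise_mean must be > 0", call. = FALSE)
  if (p$mv_rate < 0 || p$mv_rate >= 1)
    stop("mv_rate must lie in [0, 1)", call. = FALSE)
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-11s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read simulation parameters from a config file
#'
#' The config is a YAML key-value file whose keys mirror the argument
#' names of [sim_params()] verbatim. Unknown keys are an error, so typos
#' in parameter sweeps fail loudly instead of silently falling back to
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `sim_params` object.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a key-value mapping", call. = FALSE)
  known <- names(formals(sim_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(sim_params, cfg)
}

# Deterministic child-seed derivation: one root seed, one child stream per
# (repetition, purpose). Purposes are small fixed codes so that e.g. the
# train and test partitions of repetition r never share a stream. The
# result always stays below 2^31 - 1.
derive_seed <- function(root, rep = 0L, purpose = 0L) {
  root <- as.integer(root) %% 1000003L
  ((root * 2039L + as.integer(rep) * 8191L + as.integer(purpose) * 131L) %%
     2147483629L) + 1L
}
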