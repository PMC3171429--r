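#' Complete one test sample using only the training data
#'
#' The evaluation protocol treats imputation of a new sample as part of
#' the classification rule: the new example is adjoined to the measured
#' training matrix, its missing values are generated from its own quality
#' mask, imputation runs on the augmented matrix, and only the completed
#' final column is kept. Test points are always completed one at a time —
#' never jointly — so the completed vector for one point can never depend
#' on any other test point.
#'
#' For the row-wise methods (ravg, knn, lls, ls) only the target genes
#' that are actually missing in `x_measured` are computed, which is
#' algebraically identical to imputing the whole augmented matrix and
#' extracting the last column. For BPCA, the sample is completed by
#' conditioning on the model fitted to the training matrix (posterior
#' factor scores from the sample's observed genes, posterior-mean fill of
#' the missing ones); set `bpca_test_refine_iter > 0` in the config to
#' additionally run warm-started refinement iterations on the augmented
#' matrix.
#'
#' @param train_measured Measured training matrix (genes x samples).
#' @param train_mask Training missing-value mask.
#' @param x_measured Numeric vector, one value per gene.
#' @param x_mask Logical vector, `TRUE` where `x_measured` is missing.
#' @param config An [impute_config()].
#' @param bpca_fit Optional cached `bpca_fit` of the training matrix
#'   (computed if needed).
#' @param targets Optional gene subset to complete (advanced: a
#'   classifier that uses 30 features only needs those 30 genes
#'   completed; values are identical to the full run for those genes).
#' @return The completed sample vector (equal to `x_measured` at observed
#'   genes; genes outside `targets` are returned as-is).
#' @export
impute_test_point <- function(train_measured, train_mask, x_measured, x_mask,
                              config, bpca_fit = NULL, targets = NULL) {
  stopifnot(length(x_measured) == nrow(train_measured),
            length(x_mask) == length(x_measured))
  if (!any(x_mask)) return(x_measured)
  if (config$method == "bpca") {
    if (is.null(bpca_fit))
      bpca_fit <- impute_bpca(train_measured, train_mask, config)$fit
    return(bpca_complete_sample(bpca_fit, train_measured, train_mask,
                                x_measured, x_mask, config))
  }
  aug <- cbind(train_measured, new = x_measured)
  aug_mask <- cbind(train_mask, new = x_mask)
  tg <- which(x_mask)
  if (!is.null(targets)) tg <- intersect(tg, as.integer(targets))
  if (length(tg) == 0L) return(x_measured)
  completed <- impute(aug, aug_mask, config = config, targets = tg)
  out <- x_measured
  out[tg] <- completed[tg, ncol(aug)]
  out
}

#' Hold-out classification error under the test-point protocol
#'
#' Applies a trained classifier to every test sample and returns the
#' misclassification fraction. When `config` is supplied (imputed
#' dataset kinds), each test point is first completed with
#' [impute_test_point()] against the classifier's stored training
#' reference; the signal and measured baselines are complete and skip
#' imputation. Completion is restricted to the classifier's feature
#' genes — the only ones the decision rule reads.
#'
#' @param classifier An [train_classifier()] object; for imputed kinds
#'   its `reference` must hold `measured`, `mask`, `config` (and
#'   optionally `bpca_fit`).
#' @param test_measured Test matrix (genes x samples).
#' @param test_labels Integer 0/1 labels.
#' @param test_mask Logical mask of missing test entries (imputed kinds).
#' @param config An [impute_config()], or `NULL` for complete baselines.
#' @return Misclassification fraction in \[0, 1\].
#' @export
holdout_error <- function(classifier, test_measured, test_labels,
                          test_mask = NULL, config = NULL) {
  stopifnot(ncol(test_measured) == length(test_labels))
  if (ncol(test_measured) == 0L) stop("empty test set", call. = FALSE)
  feats <- classifier$features
  if (is.null(config)) {
    X <- t(test_measured[feats, , drop = FALSE])
  } else {
    ref <- classifier$reference
    if (is.null(ref))
      stop("classifier lacks the training reference needed for test-point imputation",
           call. = FALSE)
    X <- matrix(0, ncol(test_measured), length(feats))
    for (j in seq_len(ncol(test_measured))) {
      xc <- impute_test_point(ref$measured, ref$mask,
                              test_measured[, j], test_mask[, j],
                              config, bpca_fit = ref$bpca_fit,
                              targets = feats)
      X[j, ] <- xc[feats]
    }
  }
  mean(predict(classifier, X) != test_labels)
}

#' Signal-referenced normalised RMS imputation error
#'
#' Root-mean-square difference between imputed and true-signal values
#' over the masked entries, divided by the population SD (divide by the
#' count, not count minus one) of the true signal over those same
#' entries. Referencing the noise-free signal rather than the measured
#' value scores how well imputation recovers the truth, not the noise;
#' the population-SD denominator makes "impute every masked entry with
#' the mean of the signal's masked values" score exactly 1.
#'
#' @param signal True-signal matrix.
#' @param imputed Completed matrix from [impute()].
#' @param mask Logical mask of the entries that were imputed; must be
#'   non-empty.
#' @return NRMSE, a non-negative scalar.
#' @export
nrmse <- function(signal, imputed, mask) {
  stopifnot(identical(dim(signal), dim(imputed)))
  check_mask(signal, mask, allow_full_rows = TRUE)
  if (!any(mask)) stop("NRMSE needs at least one masked entry", call. = FALSE)
  s <- signal[mask]
  denom <- sqrt(mean((s - mean(s))^2))
  if (denom == 0)
    stop("signal SD over masked entries is zero; NRMSE undefined", call. = FALSE)
  sqrt(mean((imputed[mask] - s)^2)) / denom
}

method_label <- function(config) {
  c(ravg = "RAVG", knn = "KNN", lls_l2 = "LLS.L2", lls_pc = "LLS.PC",
    ls = "LS", bpca = "BPCA")[[config$method]]
}

as_impute_configs <- function(methods) {
  cfgs <- lapply(methods, function(m) {
    if (inherits(m, "impute_config")) m else impute_config(m)
  })
  names(cfgs) <- vapply(cfgs, method_label, character(1))
  cfgs
}

# One repetition of one condition: simulate, impute, select, train,
# evaluate. Returns a tibble of result records.
run_repetition <- function(params, repetition, configs,
                           fs_methods, rules, feature_sizes,
                           stage1_size = 100L, mc_points = 100L) {
  train <- simulate_dataset(params, "train", repetition = repetition)
  test <- simulate_dataset(params, "test", shared = train,
                           repetition = repetition)
  views <- list(signal = list(train_x = train$signal, test_x = test$signal,
                              config = NULL, nrmse = NA_real_),
                orgn = list(train_x = train$measured, test_x = test$measured,
                            config = NULL, nrmse = NA_real_))
  for (nm in names(configs)) {
    cfg <- configs[[nm]]
    fit <- NULL
    if (cfg$method == "bpca") {
      res <- impute_bpca(train$measured, train$mask, cfg)
      completed <- res$completed
      fit <- res$fit
    } else {
      completed <- impute(train$measured, train$mask, config = cfg)
    }
    views[[nm]] <- list(train_x = completed, test_x = test$measured,
                        config = cfg, bpca_fit = fit,
                        nrmse = nrmse(train$signal, completed, train$mask))
  }

  rows <- list()
  for (kind in names(views)) {
    v <- views[[kind]]
    ref <- if (!is.null(v$config))
      list(measured = train$measured, mask = train$mask,
           config = v$config, bpca_fit = v$bpca_fit)
    for (fs in fs_methods) {
      for (rule in rules) {
        for (size in feature_sizes) {
          feats <- if (fs == "ttest") {
            select_top_t(v$train_x, train$labels, size)
          } else {
            two_stage_select(v$train_x, train$labels,
                             stage1_size = min(stage1_size, params$n_genes),
                             target_size = size, rule = rule,
                             mc_points = mc_points,
                             seed = derive_seed(params$seed, repetition, 11L))
          }
          clf <- train_classifier(v$train_x, train$labels, feats, rule,
                                  reference = ref)
          err <- holdout_error(clf, v$test_x, test$labels,
                               test_mask = test$mask, config = v$config)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            repetition = repetition, dataset_kind = kind, fs_method = fs,
            rule = rule, n_features = as.integer(size),
            mv_rate = params$mv_rate, noise_mean = params$noise_mean,
            block_sd = params$block_sd, block_corr = params$block_corr,
            mask_mode = params$mask_mode, seed = params$seed,
            error = err, nrmse = v$nrmse)
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Run one simulation condition
#'
#' Executes the full per-repetition protocol for one parameter setting:
#' generate a training and an independent test partition (sharing fold
#' changes, covariance and quality threshold), impute the masked training
#' matrix with each configured method, and for every dataset kind
#' (`signal`, `orgn` = measured, one per imputation method) run each
#' feature-selection method x classification rule x feature-set size,
#' evaluating hold-out error on the matching test view — like-on-like:
#' signal classifiers are tested on signal test data, measured on
#' measured, and imputed kinds complete each test point from the training
#' data. The signal-referenced NRMSE of each imputed training matrix is
#' recorded alongside.
#'
#' A failing repetition is logged and skipped; completed repetitions are
#' retained.
#'
#' @param params A [sim_params()] object.
#' @param methods Imputation methods: tokens or [impute_config()]s.
#' @param fs_methods Subset of `c("ttest", "sffs")`.
#' @param rules Subset of `c("lda", "3nn", "svm")`.
#' @param feature_sizes Integer vector of feature-set sizes.
#' @param repetitions Number of repetitions (indices `1:repetitions`).
#' @param rep_indices Explicit repetition indices to run (overrides
#'   `repetitions`; used by [run_plan()] to run and resume single
#'   repetitions).
#' @param stage1_size t-test pool size ahead of SFFS (default 100).
#' @param mc_points Monte-Carlo draws for 3NN bolstering.
#' @return A `condition_result`: list with `records` (tibble of result
#'   rows) and `nrmse` (per-method mean/SD NRMSE over repetitions).
#' @examples
#' \donttest{
#' p <- sim_params(n_genes = 60, n_markers = 6, n_train = 20, n_test = 30,
#'                 block_size = 10, seed = 3)
#' cr <- run_condition(p, methods = "ravg", rules = "lda",
#'                     feature_sizes = 5, repetitions = 2)
#' cr$records
#' }
#' @export
run_condition <- function(params, methods = c("ravg", "knn", "lls_l2",
                                              "lls_pc", "ls", "bpca"),
                          fs_methods = "ttest", rules = c("lda", "3nn", "svm"),
                          feature_sizes = c(5L, 10L, 15L, 20L, 25L, 30L),
                          repetitions = 20L, stage1_size = 100L,
                          mc_points = 100L, rep_indices = NULL) {
  configs <- as_impute_configs(as.list(methods))
  reps <- if (is.null(rep_indices)) seq_len(repetitions) else
    as.integer(rep_indices)
  mv_log("info", sprintf("condition: noise %.2g, sd %.2g, corr %.2g, mv %.2g (%s), %d rep(s)",
                         params$noise_mean, params$block_sd, params$block_corr,
                         params$mv_rate, params$mask_mode, length(reps)))
  out <- list()
  for (r in reps) {
    rec <- tryCatch(
      run_repetition(params, r, configs, fs_methods, rules, feature_sizes,
                     stage1_size, mc_points),
      error = function(e) {
        mv_log("warn", sprintf("repetition %d aborted: %s", r, conditionMessage(e)))
        NULL
      })
    out[[length(out) + 1L]] <- rec
  }
  records <- dplyr::bind_rows(out)
  nrmse_summary <- records |>
    dplyr::filter(!is.na(.data$nrmse)) |>
    dplyr::distinct(.data$repetition, .data$dataset_kind, .data$nrmse) |>
    dplyr::group_by(.data$dataset_kind) |>
    dplyr::summarise(mean_nrmse = mean(.data$nrmse),
                     sd_nrmse = sd(.data$nrmse), n = dplyr::n(),
                     .groups = "drop")
  structure(list(records = records, nrmse = nrmse_summary),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("condition_result: %d record(s), %d repetition(s)\n",
              nrow(x$records), length(unique(x$records$repetition))))
  if (nrow(x$nrmse) > 0) print(x$nrmse)
  invisible(x)
}

#' Define a factorial experiment plan
#'
#' A plan crosses lists of simulation-condition values (noise level,
#' block SD, block correlation, MV rate, masking mode) with the methods,
#' feature-selection methods, rules and feature sizes to evaluate. The
#' default grids are the study's sweep; `repetitions` defaults to a
#' desk-scale 20 (the full-scale study uses 150 — set it explicitly for
#' a long run).
#'
#' @param noise_mean,block_sd,block_corr,mv_rate,mask_mode Vectors of
#'   condition values to cross.
#' @param methods,fs_methods,rules,feature_sizes As in [run_condition()].
#' @param repetitions Repetitions per condition.
#' @param root_seed Root seed; every (condition, repetition) stream is
#'   derived from it.
#' @param base_params Baseline [sim_params()] supplying the fixed fields
#'   (geometry, fold-change distribution, block size).
#' @param stage1_size,mc_points As in [run_condition()].
#' @return An `experiment_plan` list.
#' @export
experiment_plan <- function(noise_mean = c(0.1, 0.2, 0.4, 0.8, 1.2, 1.6),
                            block_sd = c(0.4, 0.8, 1.2),
                            block_corr = c(0.1, 0.5, 0.9),
                            mv_rate = c(0.01, 0.05, 0.10, 0.15, 0.20, 0.25),
                            mask_mode = "quality",
                            methods = c("ravg", "knn", "lls_l2", "lls_pc",
                                        "ls", "bpca"),
                            fs_methods = "ttest",
                            rules = c("lda", "3nn", "svm"),
                            feature_sizes = c(5L, 10L, 15L, 20L, 25L, 30L),
                            repetitions = 20L, root_seed = 1L,
                            base_params = sim_params(),
                            stage1_size = 100L, mc_points = 100L) {
  stopifnot(length(noise_mean) > 0, length(block_sd) > 0,
            length(block_corr) > 0, length(mv_rate) > 0,
            length(mask_mode) > 0, repetitions >= 1L)
  grid <- expand.grid(noise_mean = noise_mean, block_sd = block_sd,
                      block_corr = block_corr, mv_rate = mv_rate,
                      mask_mode = mask_mode, stringsAsFactors = FALSE)
  structure(list(grid = tibble::as_tibble(grid), methods = methods,
                 fs_methods = fs_methods, rules = rules,
                 feature_sizes = feature_sizes,
                 repetitions = as.integer(repetitions),
                 root_seed = as.integer(root_seed),
                 base_params = base_params,
                 stage1_size = as.integer(stage1_size),
                 mc_points = as.integer(mc_points)),
            class = "experiment_plan")
}

#' Run an experiment plan, streaming results to a TSV
#'
#' Iterates the factorial grid of an [experiment_plan()], running each
#' (condition, repetition) independently under a deterministically
#' derived seed and appending its result rows to `path` as they
#' complete. With `resume = TRUE`, (condition, repetition) pairs already
#' present in the file are skipped, so an interrupted run resumed with
#' the same plan produces the identical final file.
#'
#' @param plan An [experiment_plan()].
#' @param path Output TSV path.
#' @param resume Skip (condition, repetition) pairs already in `path`.
#' @return The results tibble, invisibly.
#' @export
run_plan <- function(plan, path, resume = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  done <- NULL
  if (resume && file.exists(path)) {
    prev <- read_results(path)
    done <- unique(prev[, c("seed", "repetition")])
  }
  started <- resume && file.exists(path)
  configs <- as.list(plan$methods)
  for (ci in seq_len(nrow(plan$grid))) {
    cond <- plan$grid[ci, ]
    params <- plan$base_params
    params$noise_mean <- cond$noise_mean
    params$block_sd <- cond$block_sd
    params$block_corr <- cond$block_corr
    params$mv_rate <- cond$mv_rate
    params$mask_mode <- cond$mask_mode
    params$seed <- derive_seed(plan$root_seed, ci, 97L)
    params <- validate_sim_params(params)
    for (r in seq_len(plan$repetitions)) {
      if (!is.null(done) &&
          any(done$seed == params$seed & done$repetition == r)) next
      cr <- run_condition(params, methods = configs,
                          fs_methods = plan$fs_methods, rules = plan$rules,
                          feature_sizes = plan$feature_sizes,
                          rep_indices = r,
                          stage1_size = plan$stage1_size,
                          mc_points = plan$mc_points)
      if (nrow(cr$records) > 0) {
        write_results(cr$records, path, append = started)
        started <- TRUE
      }
    }
  }
  invisible(read_results(path))
}
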