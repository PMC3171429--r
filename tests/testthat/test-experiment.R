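test_that("NRMSE matches its definition on hand-computable cases", {
  signal <- matrix(c(0, 2, 5, 5), 2, 2)
  imputed <- matrix(c(1, 1, 5, 5), 2, 2)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(nrmse(signal, imputed, mask), 1)          # RMS 1 / SD 1
  expect_equal(nrmse(signal, signal, mask), 0)
  # mean-filling the masked signal values scores exactly 1
  imputed2 <- signal; imputed2[mask] <- mean(signal[mask])
  expect_equal(nrmse(signal, imputed2, mask), 1)
  expect_error(nrmse(signal, imputed, matrix(FALSE, 2, 2)), "one masked")
  flat <- matrix(1, 2, 2)
  expect_error(nrmse(flat, imputed, mask), "zero")
})

test_that("test points are completed from the training data alone", {
  p <- small_params(seed = 71)
  tr <- simulate_dataset(p, "train")
  te <- simulate_dataset(p, "test", shared = tr)
  cfg <- impute_config("ravg")
  # a complete point is returned unchanged
  clean <- te$measured[, which.max(colSums(!te$mask))]
  expect_identical(impute_test_point(tr$measured, tr$mask, clean,
                                     rep(FALSE, p$n_genes), cfg), clean)
  # RAVG fill equals the augmented observed row mean
  j <- which.max(colSums(te$mask))
  x <- te$measured[, j]; xm <- te$mask[, j]
  got <- impute_test_point(tr$measured, tr$mask, x, xm, cfg)
  g <- which(xm)[[1]]
  expect_equal(unname(got[g]), mean(tr$measured[g, !tr$mask[g, ]]))
  expect_identical(got[!xm], x[!xm])
})

test_that("completion of one point never depends on other test points", {
  p <- small_params(seed = 72, mv_rate = 0.15)
  tr <- simulate_dataset(p, "train")
  te <- simulate_dataset(p, "test", shared = tr)
  for (method in c("knn", "lls_l2", "bpca")) {
    cfg <- impute_config(method, k_neighbors = 5, k_candidates = 5)
    fit <- if (method == "bpca") impute_bpca(tr$measured, tr$mask, cfg)$fit
    one_by_one <- sapply(seq_len(ncol(te$measured)), function(j)
      impute_test_point(tr$measured, tr$mask, te$measured[, j], te$mask[, j],
                        cfg, bpca_fit = fit))
    shuffled <- sample(ncol(te$measured))
    redo <- sapply(shuffled, function(j)
      impute_test_point(tr$measured, tr$mask, te$measured[, j], te$mask[, j],
                        cfg, bpca_fit = fit))
    expect_identical(redo, one_by_one[, shuffled], label = method)
  }
})

test_that("hold-out error counts misclassifications under the protocol", {
  p <- small_params(seed = 73)
  tr <- simulate_dataset(p, "train")
  te <- simulate_dataset(p, "test", shared = tr)
  feats <- select_top_t(tr$signal, tr$labels, 5)
  clf <- train_classifier(tr$signal, tr$labels, feats, "lda")
  # relabelling the training data as test: essentially perfect resubstitution
  expect_equal(holdout_error(clf, tr$signal, tr$labels), 0)
  # order invariance
  e1 <- holdout_error(clf, te$signal, te$labels)
  o <- sample(ncol(te$signal))
  expect_equal(holdout_error(clf, te$signal[, o], te$labels[o]), e1)
  # a constant rule errs on exactly half of a balanced test set
  const <- clf
  const$parameters$w <- c(0, 0, 0, 0, 0)
  const$parameters$b <- -1          # always class 0
  expect_equal(holdout_error(const, te$signal, te$labels), 0.5)
})

test_that("hold-out error with imputation equals per-point completion + prediction", {
  p <- small_params(seed = 74)
  tr <- simulate_dataset(p, "train")
  te <- simulate_dataset(p, "test", shared = tr)
  cfg <- impute_config("knn", k_neighbors = 5)
  completed <- impute(tr$measured, tr$mask, config = cfg)
  feats <- select_top_t(completed, tr$labels, 5)
  clf <- train_classifier(completed, tr$labels, feats, "lda",
                          reference = list(measured = tr$measured,
                                           mask = tr$mask, config = cfg))
  err <- holdout_error(clf, te$measured, te$labels, te$mask, cfg)
  preds <- vapply(seq_len(ncol(te$measured)), function(j) {
    xc <- impute_test_point(tr$measured, tr$mask, te$measured[, j],
                            te$mask[, j], cfg)
    predict(clf, xc[feats])
  }, integer(1))
  expect_equal(err, mean(preds != te$labels))
  # dropping test points leaves the remaining predictions unchanged
  keep <- seq(1, ncol(te$measured), by = 2)
  expect_equal(holdout_error(clf, te$measured[, keep], te$labels[keep],
                             te$mask[, keep], cfg),
               mean(preds[keep] != te$labels[keep]))
})

test_that("run_condition produces the full record grid with NRMSE on imputed kinds only", {
  p <- small_params(seed = 75)
  cr <- run_condition(p, methods = "ravg", fs_methods = "ttest",
                      rules = "lda", feature_sizes = c(3L, 5L),
                      repetitions = 1)
  expect_equal(nrow(cr$records), 6L)   # 3 kinds x 1 fs x 1 rule x 2 sizes
  expect_setequal(unique(cr$records$dataset_kind), c("signal", "orgn", "RAVG"))
  expect_true(all(is.na(cr$records$nrmse[cr$records$dataset_kind != "RAVG"])))
  expect_true(all(!is.na(cr$records$nrmse[cr$records$dataset_kind == "RAVG"])))
  expect_true(all(cr$records$error >= 0 & cr$records$error <= 1))
  expect_equal(nrow(cr$nrmse), 1L)
  # determinism
  cr2 <- run_condition(p, methods = "ravg", fs_methods = "ttest",
                       rules = "lda", feature_sizes = c(3L, 5L),
                       repetitions = 1)
  expect_identical(cr$records, cr2$records)
})

test_that("run_plan streams the grid and resume reproduces an uninterrupted run", {
  plan <- experiment_plan(noise_mean = 0.8, block_sd = 0.4,
                          block_corr = c(0.1, 0.9), mv_rate = 0.1,
                          methods = "ravg", fs_methods = "ttest",
                          rules = "lda", feature_sizes = 4L,
                          repetitions = 2L, root_seed = 5L,
                          base_params = small_params())
  full_path <- withr::local_tempfile(fileext = ".tsv")
  res <- run_plan(plan, full_path)
  expect_equal(nrow(res), 2L * 2L * 3L)   # conditions x reps x kinds
  # interrupted run: first only one repetition everywhere, then resume
  part_path <- withr::local_tempfile(fileext = ".tsv")
  plan1 <- plan; plan1$repetitions <- 1L
  run_plan(plan1, part_path)
  res2 <- run_plan(plan, part_path, resume = TRUE)
  key <- function(d) dplyr::arrange(d, .data$seed, .data$repetition,
                                    .data$dataset_kind)
  expect_equal(as.data.frame(key(res2)), as.data.frame(key(res)))
})

test_that("summaries aggregate errors and NRMSE by group", {
  rec <- tibble::tibble(
    repetition = rep(1:3, 2), dataset_kind = rep(c("orgn", "BPCA"), each = 3),
    fs_method = "ttest", rule = "lda", n_features = 10L, mv_rate = 0.1,
    noise_mean = 0.8, block_sd = 0.4, block_corr = 0.5,
    mask_mode = "quality", seed = 1L,
    error = c(0.2, 0.3, 0.4, 0.1, 0.1, 0.1),
    nrmse = c(NA, NA, NA, 0.9, 1.0, 1.1))
  s <- summarize_results(rec)
  expect_equal(nrow(s), 2L)
  expect_equal(s$mean_error[s$dataset_kind == "orgn"], 0.3)
  expect_equal(s$mean_nrmse[s$dataset_kind == "BPCA"], 1.0)
  expect_equal(s$n_reps, c(3L, 3L))
  one <- summarize_results(rec[1, ])
  expect_equal(one$mean_error, 0.2)
  expect_error(summarize_results(rec[0, ]), "no result rows")
})

test_that("plot helpers return ggplot objects with one point per condition", {
  rec <- tidyr::expand_grid(repetition = 1:2, dataset_kind = c("BPCA", "LS"),
                            mv_rate = c(0.05, 0.1))
  rec <- dplyr::mutate(rec, fs_method = "ttest", rule = "lda",
                       n_features = 5L, noise_mean = 0.8, block_sd = 0.4,
                       block_corr = 0.5, mask_mode = "quality", seed = 1L,
                       error = 0.2, nrmse = runif(dplyr::n()))
  pl <- plot_nrmse_curves(rec)
  expect_s3_class(pl, "ggplot")
  expect_equal(nrow(pl$data), 4L)   # one point per (method, mv_rate)
  s <- summarize_results(rec)
  expect_s3_class(plot_error_curves(s, x = "mv_rate"), "ggplot")
})
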