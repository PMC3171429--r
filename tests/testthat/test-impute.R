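test_that("every method is the identity on an empty mask and preserves observed cells", {
  inst <- random_instance(12, 8, n_missing = 6, seed = 11)
  none <- matrix(FALSE, 12, 8)
  for (m in c("ravg", "knn", "lls_l2", "lls_pc", "ls", "bpca")) {
    expect_identical(unname(impute(inst$x, none, m)), inst$x, label = m)
    out <- impute(inst$x, inst$mask, m, k_neighbors = 4, k_candidates = 5)
    expect_identical(out[!inst$mask], inst$x[!inst$mask], label = m)
    expect_true(all(is.finite(out)), label = m)
  }
})

test_that("row-average fills with the observed mean", {
  x <- rbind(c(1, 2, 3, 0), c(5, 5, 5, 0), c(0, 0, 4, 9))
  mask <- rbind(c(FALSE, FALSE, FALSE, TRUE),
                c(FALSE, FALSE, FALSE, TRUE),
                c(FALSE, TRUE, FALSE, TRUE))
  out <- impute_ravg(x, mask)
  expect_equal(out[1, 4], 2)
  expect_equal(out[2, 4], 5)
  expect_equal(out[3, c(2, 4)], c(2, 2))
  expect_error(impute_ravg(rbind(c(1, 2)), rbind(c(TRUE, TRUE))),
               "all values missing")
})

test_that("KNN candidates are eligible, ranked by scaled distance, and clamp at K", {
  x <- rbind(t1 = c(1, 2, 3, 0),
             same = c(1, 2, 3, 9),
             far = c(5, 5, 5, 7),
             holed = c(1, 2, 3, 0))
  mask <- matrix(FALSE, 4, 4)
  mask[1, 4] <- TRUE   # target missing at position 4
  mask[4, 4] <- TRUE   # ineligible: missing where the target is missing
  cand <- knn_candidates(x, mask, 1, K = 10)
  expect_equal(cand$gene, c(2, 3))            # clamped to the 2 eligible
  expect_equal(cand$distance[1], 0)           # identical on observed part
  out <- impute(x, mask, "knn", k_neighbors = 1)
  expect_equal(out[1, 4], 9)                  # K = 1: nearest neighbour value
})

test_that("KNN weights are reciprocal-distance and convex", {
  # two candidates at scaled distances exactly 1 and 3
  x <- rbind(c(0, 0, 0, 0, 0),
             c(1, 1, 1, 1, 10),
             c(3, 3, 3, 3, 20))
  mask <- matrix(FALSE, 3, 5)
  mask[1, 5] <- TRUE
  out <- impute(x, mask, "knn", k_neighbors = 2)
  expect_equal(out[1, 5], 0.75 * 10 + 0.25 * 20, tolerance = 1e-5)
  # convexity on a random instance with all-eligible candidates
  inst <- random_instance(10, 8, n_missing = 3, seed = 12)
  mask1 <- matrix(FALSE, 10, 8)
  mask1[cbind(1:3, c(2, 5, 7))] <- TRUE
  out1 <- impute(inst$x, mask1, "knn", k_neighbors = 9)
  for (i in 1:3) {
    p <- c(2, 5, 7)[i]
    expect_gte(out1[i, p], min(inst$x[-i, p]))
    expect_lte(out1[i, p], max(inst$x[-i, p]))
  }
})

test_that("KNN equals exhaustive-enumeration weighted averages", {
  for (seed in 1:5) {
    inst <- random_instance(10, 8, n_missing = 6, seed = seed)
    for (K in c(3, 10)) {
      expect_equal(impute(inst$x, inst$mask, "knn", k_neighbors = K),
                   knn_oracle(inst$x, inst$mask, K), tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
})

test_that("LLS recovers exact linear relations and minimum-norm LS solutions", {
  # target = 2 x candidate: the LS solution is w = 2 exactly
  set.seed(13)
  cand <- rnorm(6)
  x <- rbind(2 * cand, cand)
  mask <- matrix(FALSE, 2, 6)
  mask[1, 6] <- TRUE
  out <- impute(x, mask, "lls_l2", k_candidates = 1)
  expect_equal(out[1, 6], 2 * cand[6], tolerance = 1e-10)

  # normal-equation oracle with the full candidate set (selection trivial)
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(10 * 14), 10, 14)
    mask <- matrix(FALSE, 10, 14)
    mask[1, c(3, 9)] <- TRUE
    out <- impute(x, mask, "lls_l2", k_candidates = 9)
    A <- x[-1, -c(3, 9)]
    w <- solve(A %*% t(A), A %*% x[1, -c(3, 9)])
    expect_equal(unname(out[1, c(3, 9)]),
                 as.numeric(t(x[-1, c(3, 9)]) %*% w), tolerance = 1e-8)
    # the solution is a local (indeed global) optimum of the LS residual
    res0 <- sum((t(A) %*% w - x[1, -c(3, 9)])^2)
    for (k in 1:20) {
      res <- sum((t(A) %*% (w + rnorm(9, sd = 0.01)) - x[1, -c(3, 9)])^2)
      expect_gte(res, res0 - 1e-12)
    }
  }
})

test_that("LLS similarity metrics rank candidates differently", {
  set.seed(14)
  base <- rnorm(8)
  x <- unname(rbind(base,
                    base + rnorm(8, sd = 0.05), # closest in L2, |corr| < 1
                    -3 * base,                  # far in L2, |corr| = 1 exactly
                    rnorm(8) * 5))
  mask <- matrix(FALSE, 4, 8)
  mask[1, 8] <- TRUE
  # correlation ranking picks the perfectly (anti-)correlated gene, and the
  # exact linear relation makes the fill exact; L2 picks the noisy twin
  pc <- impute(x, mask, "lls_pc", k_candidates = 1)
  expect_equal(pc[1, 8], base[8], tolerance = 1e-10)
  l2 <- impute(x, mask, "lls_l2", k_candidates = 1)
  expect_gt(abs(l2[1, 8] - pc[1, 8]), 1e-6)
})

test_that("LS matches an independent implementation and its special cases", {
  # single candidate: the regression estimate itself
  set.seed(15)
  cand <- rnorm(7)
  target <- 1.5 + 2 * cand + rnorm(7, sd = 0.1)
  x <- rbind(target, cand)
  mask <- matrix(FALSE, 2, 7)
  mask[1, 7] <- TRUE
  out <- impute(x, mask, "ls", k_candidates = 1)
  b <- cov(target[-7], cand[-7]) / var(cand[-7])
  a <- mean(target[-7]) - b * mean(cand[-7])
  expect_equal(out[1, 7], a + b * cand[7], tolerance = 1e-10)

  # exact affine relation: recovered exactly
  x2 <- rbind(3 - 2 * cand, cand)
  out2 <- impute(x2, mask, "ls", k_candidates = 1)
  expect_equal(out2[1, 7], 3 - 2 * cand[7], tolerance = 1e-6)

  # full-path oracle with the complete candidate set
  for (seed in 1:4) {
    inst <- random_instance(9, 10, n_missing = 4, seed = seed + 20)
    expect_equal(impute(inst$x, inst$mask, "ls", k_candidates = 8),
                 ls_oracle_all_candidates(inst$x, inst$mask),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("LS stays within the convex hull of its per-candidate estimates", {
  set.seed(16)
  x <- matrix(rnorm(8 * 9), 8, 9)
  mask <- matrix(FALSE, 8, 9)
  mask[2, 4] <- TRUE
  out <- impute(x, mask, "ls", k_candidates = 7)
  filled <- impute_ravg(x, mask)
  ests <- sapply(setdiff(1:8, 2), function(j) {
    cj <- filled[j, -4]
    b <- cov(x[2, -4], cj) / var(cj)
    mean(x[2, -4]) - b * mean(cj) + b * filled[j, 4]
  })
  expect_gte(out[2, 4], min(ests) - 1e-12)
  expect_lte(out[2, 4], max(ests) + 1e-12)
})

test_that("imputation is equivariant to gene permutations", {
  inst <- random_instance(12, 7, n_missing = 6, seed = 17)
  set.seed(18)
  perm <- sample(12)
  for (m in c("ravg", "knn", "lls_l2", "ls")) {
    out <- impute(inst$x, inst$mask, m, k_neighbors = 4, k_candidates = 5)
    outp <- impute(inst$x[perm, ], inst$mask[perm, ], m,
                   k_neighbors = 4, k_candidates = 5)
    expect_equal(outp, out[perm, ], tolerance = 1e-12, ignore_attr = TRUE,
                 label = m)
  }
})

test_that("LLS and BPCA reconstruct exactly low-rank data to 1e-4 relative error", {
  set.seed(19)
  L <- matrix(rnorm(15 * 2), 15, 2)
  F <- matrix(rnorm(10 * 2), 10, 2)
  x <- L %*% t(F)
  mask <- matrix(FALSE, 15, 10)
  mask[1, c(2, 6, 9)] <- TRUE        # one target gene, candidates all clean
  scale <- max(abs(x))
  lls <- impute(x, mask, "lls_l2", k_candidates = 5)
  expect_lt(max(abs(lls - x)[mask]) / scale, 1e-4)
  # the exact-recovery limit needs a tight stopping rule: the default
  # 1e-4 fill-change tolerance stops well before machine-level recovery
  bp <- suppressWarnings(impute(x, mask, "bpca", bpca_tol = 1e-7,
                                bpca_max_iter = 3000))
  expect_lt(max(abs(bp - x)[mask]) / scale, 1e-4)
})

test_that("unknown methods and too-small matrices are refused", {
  x <- matrix(rnorm(4), 2, 2)
  expect_error(impute_config("pmm"), "arg")
  expect_error(impute(x[1, , drop = FALSE], matrix(FALSE, 1, 2), "ravg"),
               "at least 2 genes")
})
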