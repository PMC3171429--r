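# Shared fixtures: small randomised matrix/mask pairs and reference
# (brute-force) implementations used as oracles.

random_instance <- function(n_genes = 10, n_samples = 8, n_missing = 5,
                            seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  mask <- matrix(FALSE, n_genes, n_samples)
  cells <- sample(n_genes * n_samples, n_missing)
  mask[cells] <- TRUE
  # keep every gene partially observed
  full <- rowSums(mask) == n_samples
  mask[full, 1] <- FALSE
  list(x = x, mask = mask)
}

small_params <- function(seed = 1, ...) {
  sim_params(n_genes = 40, n_markers = 5, n_train = 20, n_test = 20,
             block_size = 10, seed = seed, ...)
}

# Exhaustive-enumeration KNN imputation: every eligible candidate's
# distance computed directly from the definition.
knn_oracle <- function(x, mask, K, eps = 1e-6) {
  out <- x
  for (t in which(rowSums(mask) > 0)) {
    tmiss <- which(mask[t, ])
    tobs <- which(!mask[t, ])
    cand <- integer(0); dd <- numeric(0)
    for (g in seq_len(nrow(x))) {
      if (g == t || any(mask[g, tmiss])) next
      J <- tobs[!mask[g, tobs]]
      if (length(J) == 0) next
      cand <- c(cand, g)
      dd <- c(dd, sqrt(sum((x[t, J] - x[g, J])^2) / length(J)))
    }
    if (length(cand) == 0) {
      out[t, tmiss] <- mean(x[t, tobs])
      next
    }
    o <- order(dd, cand)[seq_len(min(K, length(cand)))]
    w <- 1 / (dd[o] + eps)
    w <- w / sum(w)
    for (p in tmiss) out[t, p] <- sum(w * x[cand[o], p])
  }
  out
}

# Independent LS-imputation reference for instances where the candidate
# set is the whole remainder (k = n_genes - 1), so ranking plays no role.
ls_oracle_all_candidates <- function(x, mask) {
  filled <- impute_ravg(x, mask)
  out <- x
  for (t in which(rowSums(mask) > 0)) {
    tobs <- which(!mask[t, ])
    tmiss <- which(mask[t, ])
    b <- x[t, tobs]
    cand <- setdiff(seq_len(nrow(x)), t)
    est <- matrix(0, length(cand), length(tmiss))
    wts <- numeric(length(cand))
    for (j in seq_along(cand)) {
      cj <- filled[cand[j], tobs]
      beta <- cov(b, cj) / var(cj)
      r2 <- cor(b, cj)^2
      est[j, ] <- mean(b) - beta * mean(cj) + beta * filled[cand[j], tmiss]
      wts[j] <- (r2 / (1 - r2 + 1e-6))^2
    }
    out[t, tmiss] <- as.numeric((wts / sum(wts)) %*% est)
  }
  out
}

sign_test_p <- function(wins, losses) {
  n <- wins + losses
  if (n == 0) return(1)
  stats::binom.test(wins, n, alternative = "greater")$p.value
}
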