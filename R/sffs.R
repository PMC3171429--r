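#' Sequential forward floating search (SFFS)
#'
#' Wrapper feature selection driven by [bolstered_error()] as the
#' criterion. Plain sequential forward selection (SFS) greedily adds the
#' feature that minimises the criterion; its weakness is that an early
#' feature can never be removed. SFFS adds a floating step: after each
#' inclusion, the "least significant" feature — the one whose removal
#' minimises the criterion — is removed, repeatedly, as long as (a) it is
#' not the feature just added and (b) the reduced set strictly beats the
#' best set of that size found so far.
#'
#' The implementation first runs plain SFS over the pool and seeds the
#' best-per-size table with the SFS sets, then runs the floating search;
#' the returned set is the best recorded at `target_size`. This makes
#' the guarantee "SFFS never returns a worse set than SFS at the same
#' size" structural. Criterion ties always break towards the lower
#' feature index, and all criterion evaluations are memoised.
#'
#' @inheritParams bolstered_error
#' @param pool Integer vector of candidate gene indices (e.g. the t-test
#'   stage-one survivors).
#' @param target_size Requested feature-set size, at most `length(pool)`.
#' @return Integer vector of `target_size` gene indices with the
#'   criterion value in `attr(, "criterion")` and the plain-SFS criterion
#'   in `attr(, "sfs_criterion")`.
#' @export
sffs_select <- function(x, labels, pool, target_size, rule = "lda",
                        mc_points = 100L, seed = 1L) {
  pool <- as.integer(pool)
  if (target_size < 1L || target_size > length(pool))
    stop("target_size must lie in [1, length(pool)]", call. = FALSE)
  memo <- new.env(parent = emptyenv())
  J <- function(S) {
    S <- sort(S)
    key <- paste(S, collapse = ",")
    if (is.null(memo[[key]]))
      memo[[key]] <- bolstered_error(x, labels, S, rule,
                                     mc_points = mc_points, seed = seed)
    memo[[key]]
  }

  # Phase 1: plain SFS, recording the best set of every size.
  best_sets <- vector("list", target_size)
  best_crit <- rep(Inf, target_size)
  A <- integer(0)
  for (k in seq_len(target_size)) {
    cand <- setdiff(pool, A)
    js <- vapply(cand, function(f) J(c(A, f)), numeric(1))
    pick <- order(js, cand)[1L]
    A <- c(A, cand[pick])
    best_sets[[k]] <- A
    best_crit[k] <- js[pick]
  }
  sfs_crit <- best_crit[target_size]

  # Phase 2: floating search.
  A <- integer(0)
  steps <- 0L
  max_steps <- 60L * target_size
  repeat {
    steps <- steps + 1L
    cand <- setdiff(pool, A)
    js <- vapply(cand, function(f) J(c(A, f)), numeric(1))
    pick <- order(js, cand)[1L]
    last_added <- cand[pick]
    A <- c(A, last_added)
    k <- length(A)
    if (js[pick] < best_crit[k]) {
      best_sets[[k]] <- A
      best_crit[k] <- js[pick]
    }
    # Conditional exclusions.
    guard <- last_added
    while (length(A) > 2L) {
      js_rm <- vapply(A, function(f) J(setdiff(A, f)), numeric(1))
      pick_rm <- order(js_rm, A)[1L]
      least <- A[pick_rm]
      if (!is.na(guard) && least == guard) break
      if (js_rm[pick_rm] < best_crit[length(A) - 1L]) {
        A <- setdiff(A, least)
        best_sets[[length(A)]] <- A
        best_crit[length(A)] <- js_rm[pick_rm]
        guard <- NA_integer_
      } else break
    }
    if (length(A) >= target_size || steps >= max_steps) break
  }
  out <- sort(best_sets[[target_size]])
  structure(out, criterion = best_crit[target_size], sfs_criterion = sfs_crit)
}

#' Two-stage feature selection
#'
#' Stage one removes most non-informative genes with the t-test filter
#' ([select_top_t()] down to `stage1_size`); stage two runs the SFFS
#' wrapper over the survivors down to `target_size`. With
#' `stage1_size == target_size` this is pure t-test selection; with
#' `stage1_size == nrow(x)` it is pure SFFS.
#'
#' @inheritParams sffs_select
#' @param stage1_size Pool size after the t-test filter (default 100).
#' @param target_size Final feature-set size.
#' @return Integer vector of `target_size` gene indices (a subset of the
#'   top-`stage1_size` genes by `|t|`).
#' @export
two_stage_select <- function(x, labels, stage1_size = 100L, target_size,
                             rule = "lda", mc_points = 100L, seed = 1L) {
  if (target_size > stage1_size || stage1_size > nrow(x))
    stop("need target_size <= stage1_size <= n_genes", call. = FALSE)
  pool <- as.integer(select_top_t(x, labels, stage1_size))
  if (stage1_size == target_size) return(structure(pool, criterion = NA_real_))
  sffs_select(x, labels, pool, target_size, rule,
              mc_points = mc_points, seed = seed)
}
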