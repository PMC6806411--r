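# Shared fixtures and independent oracles, built in code at test time.

# Small deterministic dataset: k independent N(0,1) descriptors, linear
# activity with optional noise.
toy_dataset <- function(n = 12, k = 3, noise_sd = 0, seed = 42,
                        beta = seq_len(k) / k, intercept = 6) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * k), n, k,
                dimnames = list(NULL, paste0("T", seq_len(k))))
    y <- intercept + drop(X %*% beta) + rnorm(n, sd = noise_sd)
    qsar_dataset(sprintf("c%02d", seq_len(n)), X, y)
  })
}

# Independent naive Kennard-Stone: O(n^3) direct maximin with the same
# lowest-index tie-break, written against the verbal definition only.
naive_kennard_stone <- function(X, n_train) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(1L, 2L); bd <- -1
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
    if (D[i, j] > bd) { bd <- D[i, j]; best <- c(i, j) }
  sel <- best
  while (length(sel) < n_train) {
    cand <- setdiff(seq_len(n), sel)
    pick <- cand[1L]; pd <- -1
    for (cc in cand) {
      mind <- min(D[cc, sel])
      if (mind > pd) { pd <- mind; pick <- cc }
    }
    sel <- c(sel, pick)
  }
  sel
}

# Brute-force retained-subset oracle for the correlation filter: the
# largest subset (lexicographically first among ties) with all pairwise
# |r| below the threshold.
brute_force_max_subset <- function(X, r_threshold) {
  k <- ncol(X)
  C <- abs(cor(X))
  best <- integer(0)
  for (m in rev(seq_len(k))) {
    combs <- utils::combn(k, m)
    for (ci in seq_len(ncol(combs))) {
      s <- combs[, ci]
      sub <- C[s, s, drop = FALSE]
      diag(sub) <- 0
      if (all(sub < r_threshold)) return(s)
    }
  }
  best
}

expect_num_equal <- function(object, expected, tol = 1e-10)
  expect_equal(object, expected, tolerance = tol)
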