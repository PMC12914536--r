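# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation.

# All permutations of 1..n, built by recursive insertion (independent of
# the package's cached generator).
oracle_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- oracle_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
          sub[, seq(pos, length.out = n - pos), drop = FALSE])
  }))
}

# Spearman rho for tie-free data via the classical d^2 formula.
oracle_rho_d2 <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Exact two-sided permutation p for Spearman rho by brute-force
# enumeration, computing each permuted rho with stats::cor on ranks.
oracle_spearman_exact <- function(x, y) {
  n <- length(x)
  P <- oracle_perms(n)
  rx <- rank(x); ry <- rank(y)
  obs <- stats::cor(rx, ry)
  rhos <- apply(P, 1L, function(p) stats::cor(rx, ry[p]))
  list(rho = obs, p = mean(abs(rhos) >= abs(obs) - 1e-12))
}

# Two-sample KS D from first principles: max |Fa - Fb| over pooled values.
oracle_ks_d <- function(a, b, side = "two-sided") {
  v <- sort(unique(c(a, b)))
  fa <- vapply(v, function(t) mean(a <= t), 1)
  fb <- vapply(v, function(t) mean(b <= t), 1)
  switch(side,
         "two-sided" = max(abs(fa - fb)),
         "greater" = max(fa - fb),
         "less" = max(fb - fa))
}

# Exact Pr(D >= d_obs) by enumerating every assignment of the pooled
# (tie-free) order statistics to group A.
oracle_ks_exact_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pool <- sort(c(a, b))
  d_obs <- oracle_ks_d(a, b)
  combos <- utils::combn(na + nb, na)
  hits <- apply(combos, 2L, function(ia) {
    d <- oracle_ks_d(pool[ia], pool[-ia])
    d >= d_obs - 1e-12
  })
  mean(hits)
}

# GSEA running sum by an explicit element-by-element loop.
oracle_gsea_es <- function(ranking, set_genes, weight_p) {
  ord <- order(ranking, decreasing = TRUE)
  r <- ranking[ord]
  hit <- names(r) %in% set_genes
  N <- length(r); Nh <- sum(hit)
  if (weight_p == 0) {
    wsum <- Nh
    w <- rep(1, N)
  } else {
    w <- abs(r)^weight_p
    wsum <- sum(w[hit])
  }
  run <- 0; mx <- -Inf; mn <- Inf
  for (i in seq_len(N)) {
    if (hit[i]) {
      run <- run + (if (wsum == 0) 1 / Nh else w[i] / wsum)
    } else {
      run <- run - 1 / (N - Nh)
    }
    if (run > mx) mx <- run
    if (run < mn) mn <- run
  }
  unname(if (mx >= -mn - 1e-9) mx else mn)
}

# Rank-then-chunk stratification oracle: assign sorted positions to
# consecutive blocks.
oracle_stratify <- function(vals, k) {
  n <- length(vals)
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  block <- rep(seq_len(k), sizes)
  lab <- integer(n)
  lab[order(vals)] <- block
  lab
}
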