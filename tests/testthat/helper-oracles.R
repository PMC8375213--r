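# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles recompute quantities from first principles (plain R
# loops over formulas) so they share no code with the implementation paths
# they check.

oracle_gini <- function(pa) 1 - (pa^2 + (1 - pa)^2)

# Cost of every single-feature split of (x, py, pi) at threshold 0.5;
# NA where a split is one-sided (rejected).
oracle_split_costs <- function(x, py, pi = rep(1, nrow(x))) {
  vapply(seq_len(ncol(x)), function(f) {
    right <- x[, f] > 0.5
    sl <- sum(pi[!right])
    sr <- sum(pi[right])
    if (sl <= 0 || sr <= 0) return(NA_real_)
    pal <- sum(pi[!right] * py[!right]) / sl
    par <- sum(pi[right] * py[right]) / sr
    (sl * oracle_gini(pal) + sr * oracle_gini(par)) / (sl + sr)
  }, numeric(1))
}

# Walk a fitted tree (grown with bootstrap off, all features per split,
# dx = 0) and verify every internal node's split is the brute-force argmin
# of the probability-weighted cost, with ties broken by lowest feature id
# and splits only accepted when they strictly beat the node impurity.
oracle_check_tree <- function(tree, x, py) {
  ok <- TRUE
  recurse <- function(node, idx) {
    f0 <- tree$feature[node + 1L]           # 0-based feature id, -1 = leaf
    sub_x <- x[idx, , drop = FALSE]
    sub_py <- py[idx]
    costs <- oracle_split_costs(sub_x, sub_py)
    parent_g <- oracle_gini(mean(sub_py))
    if (f0 < 0) {
      # terminal: no candidate may strictly beat the node impurity
      # (unless a stopping rule such as min_samples_split fired; the
      # checks below use min_samples_split = 2, so only purity applies)
      if (length(idx) >= 2 && any(!is.na(costs)))
        ok <<- ok && (min(costs, na.rm = TRUE) >= parent_g - 1e-12)
      return(invisible())
    }
    chosen <- f0 + 1L
    stopifnot(!is.na(costs[chosen]))
    best <- min(costs, na.rm = TRUE)
    ok <<- ok && (costs[chosen] <= best + 1e-12) &&
      (costs[chosen] < parent_g) &&
      (chosen == min(which(!is.na(costs) & costs <= best + 1e-12)))
    right <- sub_x[, chosen] > 0.5
    recurse(tree$left[node + 1L], idx[!right])
    recurse(tree$right[node + 1L], idx[right])
  }
  recurse(0L, seq_len(nrow(x)))
  ok
}

# Small reproducible labelled dataset: planted two-bit signal plus noise bits.
make_toy_dataset <- function(n = 120, p = 12, sigma = 0.3, seed = 42,
                             threshold = 5) {
  set.seed(seed)
  x <- matrix(rbinom(n * p, 1, 0.4), n, p,
              dimnames = list(sprintf("C%03d", seq_len(n)),
                              sprintf("F%02d", seq_len(p))))
  latent <- threshold - 1 + 1.2 * x[, 1] + 0.8 * x[, 2] +
    rnorm(n, 0, 0.4)
  observed <- latent + rnorm(n, 0, sigma)
  list(x = x, observed = observed,
       delta_y = delta_y(observed, threshold, sigma),
       hard = as.numeric(observed >= threshold))
}

# Default-condition synthetic train/test pair for grid benchmarks.
grid_factory <- function(seed) {
  list(train = generate_bioactivity(synthetic_spec(seed = seed)),
       test = generate_bioactivity(synthetic_spec(seed = seed + 1000L)))
}

# Write a small activity CSV and return its path.
write_toy_activity_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
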