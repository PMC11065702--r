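# Small independent oracles shared across test files. Each reimplements a
# definition from first principles (enumeration, closed form or brute force)
# so that the package code path is checked against something it does not use.

# Brute-force Benjamini-Hochberg by the step-up definition.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  padj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(p[ord][i:m] * m / (i:m)))
  }, 0)
  out <- numeric(m)
  out[ord] <- padj_sorted
  out
}

# Two-sided Fisher p by full enumeration of the hypergeometric support:
# sum the probabilities of all tables (with the observed margins) that are
# no more probable than the observed one.
fisher_brute <- function(a, b, cc, d) {
  m <- a + cc          # annotated genes
  n <- b + d           # non-annotated
  k <- a + b           # query size
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# All permutations of 1..n (n! rows).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# All set partitions of 1..n as membership vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    i <- length(prefix) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1)) {
      rec(c(prefix, lab), max(maxlab, lab))
    }
  }
  rec(integer(0), 0L)
  out
}

# Maximum-modularity partition of a small graph by exhaustive search.
best_modularity_partition <- function(graph) {
  parts <- all_partitions(igraph::vcount(graph))
  mods <- vapply(parts, function(p) igraph::modularity(graph, p), 0)
  list(membership = parts[[which.max(mods)]], modularity = max(mods))
}

# Monte-Carlo-free Spearman rho on two vectors from the rank formula.
spearman_brute <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Adjusted Rand index between two labelings (contingency-table formula).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Small default config for fast end-to-end tests.
test_config <- function(...) {
  simulation_config(n_genes = 300, n_replicates = 3, seed = 42, ...)
}
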