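# Independent oracles used to check the package's statistics. Each is a
# deliberately naive implementation of the defining formula, kept free of the
# code paths it verifies.

# Exact hypergeometric pmf as a ratio of binomial coefficients. For N <= 30
# every choose() here is an exact integer below 2^53, so the ratio is exact
# to double precision.
oracle_hyper_pmf <- function(N, K, n, k) {
  if (k < 0 || k > K || n - k < 0 || n - k > N - K) return(0)
  choose(K, k) * choose(N - K, n - k) / choose(N, n)
}

oracle_p_over <- function(N, K, n, k) {
  sum(vapply(k:min(K, n), function(i) oracle_hyper_pmf(N, K, n, i), 0))
}

oracle_p_under <- function(N, K, n, k) {
  sum(vapply(0:k, function(i) oracle_hyper_pmf(N, K, n, i), 0))
}

# Benjamini-Hochberg step-up computed literally from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(1, q)
  out
}

# Hoeffding's D by literal double loops over the count-based definition:
# phi(a, b) = 1 if a < b, 1/2 if a == b, 0 otherwise;
# Q_i = 1 + sum_{j != i} phi(x_j, x_i) phi(y_j, y_i);
# R_i = 1 + sum_{j != i} phi(x_j, x_i) (mid-ranks), same for S_i.
oracle_hoeffding_d <- function(x, y) {
  n <- length(x)
  phi <- function(a, b) (a < b) + 0.5 * (a == b)
  Q <- R <- S <- numeric(n)
  for (i in seq_len(n)) {
    qi <- ri <- si <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      qi <- qi + phi(x[j], x[i]) * phi(y[j], y[i])
      ri <- ri + phi(x[j], x[i])
      si <- si + phi(y[j], y[i])
    }
    Q[i] <- 1 + qi
    R[i] <- 1 + ri
    S[i] <- 1 + si
  }
  D1 <- sum((Q - 1) * (Q - 2))
  D2 <- sum((R - 1) * (R - 2) * (S - 1) * (S - 2))
  D3 <- sum((R - 2) * (S - 2) * (Q - 1))
  30 * ((n - 2) * (n - 3) * D1 + D2 - 2 * (n - 2) * D3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

# Exact one-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to the two groups (tie-free data only).
oracle_mw_p_less <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) # U statistic of the first group
  u_obs <- u_of(x, y)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mean(us <= u_obs)
}

# Depth of every tip/node from the root, by summing edges along the path.
oracle_node_depth <- function(tree, node) {
  d <- 0
  while (TRUE) {
    e <- which(tree$edge[, 2] == node)
    if (length(e) == 0) break
    d <- d + tree$edge.length[e]
    node <- tree$edge[e, 1]
  }
  d
}

# Patristic distance between two tips as 2 * (height - depth of their MRCA),
# valid on ultrametric trees.
oracle_ultra_dist <- function(tree, a, b) {
  ia <- which(tree$tip.label == a)
  ib <- which(tree$tip.label == b)
  h <- max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
  m <- ape::getMRCA(tree, c(ia, ib))
  2 * (h - oracle_node_depth(tree, m))
}

# Small fixed ultrametric fixture trees, built in code.
fixture_tree <- function(n = 10, seed = 42, depth = 1) {
  withr::with_seed(seed, {
    tr <- ape::rphylo(n, birth = 1, death = 0)
    tr$edge.length <- tr$edge.length * (depth / max(ape::node.depth.edgelength(tr)))
    tr$tip.label <- sprintf("t%02d", seq_len(n))
    tr
  })
}

small_config <- function(seed = 1, ...) {
  synthetic_config(n_families = 12, n_species = 48, tips_per_family = c(1, 8),
                   n_obligate = 6, n_facultative = 8,
                   zone_richness = c(14, 10, 8, 5), n_plots = 12,
                   seed = seed, ...)
}
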