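# Independent brute-force oracles used across test files. These are
# deliberately naive implementations that never share code with the
# package functions they check.

# chi-square on an arbitrary contingency table, cell by cell
oracle_pearson_chisq <- function(tab) {
  total <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / total
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

# median-table counts built with an explicit loop
oracle_median_table <- function(groups) {
  med <- median(unlist(groups))
  tab <- matrix(0, 2, length(groups))
  for (g in seq_along(groups)) {
    for (v in groups[[g]]) {
      if (v > med) tab[1, g] <- tab[1, g] + 1 else tab[2, g] <- tab[2, g] + 1
    }
  }
  tab
}

# hypergeometric Z for the two-sample median test, longhand
oracle_median_z <- function(a, b) {
  med <- median(c(a, b))
  a_above <- sum(a > med)
  m <- sum(c(a, b) > med)
  N <- length(a) + length(b)
  na <- length(a)
  e <- na * m / N
  v <- na * (N - na) * m * (N - m) / (N^2 * (N - 1))
  (a_above - e) / sqrt(v)
}

# rank-sum statistic and exact two-sided p by full enumeration of all
# group labelings (pooled n must be small)
oracle_wilcoxon_exact <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  W_obs <- sum(r[seq_len(nx)])
  combs <- combn(length(pooled), nx)
  Ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- mean(Ws)
  p <- min(1, 2 * min(mean(Ws <= W_obs), mean(Ws >= W_obs)))
  list(W = W_obs, p = p, null_Ws = Ws)
}

# paralogue families by repeated transitive closure over an adjacency
# matrix (no graph library)
oracle_families <- function(edges, universe) {
  n <- length(universe)
  adj <- diag(n) > 0
  rownames(adj) <- colnames(adj) <- universe
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges$gene_a[i]; b <- edges$gene_b[i]
      adj[a, b] <- adj[b, a] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  membership <- integer(n)
  fam <- 0
  for (i in seq_len(n)) {
    if (membership[i] == 0) {
      fam <- fam + 1
      membership[adj[i, ]] <- fam
    }
  }
  split(universe, membership)
}

# small random SNP-like data frame for regression checks
make_records <- function(n, slope, intercept = 0.3, noise_sd = 0.02,
                         weights = NULL, seed = 1) {
  set.seed(seed)
  ratio <- -runif(n, 0.2, 3)
  if (is.null(weights)) weights <- runif(n, 0.5, 2)
  data.frame(
    ratio = ratio,
    allele_freq = intercept + slope * ratio + rnorm(n, 0, noise_sd),
    weight = weights)
}
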