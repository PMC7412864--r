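# Independent brute-force references used as oracles across the suite.

# Manhattan distances by explicit double loop
naive_manhattan <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(abs(m[i, ] - m[j, ]))
    }
  }
  d
}

# O(n^3) complete-linkage agglomerator: clusters as index sets, at each step
# merge the pair with minimal max cross-pair distance, record that height
naive_complete_linkage_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA_integer_
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# canonical form of a partition: relabel clusters by first appearance
canonical_partition <- function(labels) {
  match(labels, unique(labels))
}

# explicit sum-of-squares one-way ANOVA F statistic
naive_anova_F <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- length(values)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ni <- tabulate(groups)
  ssb <- sum(ni * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# a small standard synthetic library used by several PLS tests
make_latent_data <- function(n = 30, p = 8, L = 3, seed = 1,
                             noise = 0) {
  set.seed(seed)
  T0 <- matrix(rnorm(n * L), n, L)
  P0 <- matrix(rnorm(p * L), p, L)
  X <- T0 %*% t(P0) + matrix(rnorm(n * p, sd = noise), n, p)
  colnames(X) <- paste0("d", seq_len(p))
  B <- matrix(rnorm(L * 2), L, 2)
  Y <- T0 %*% B
  colnames(Y) <- c("e1", "e2")
  list(X = X, Y = Y, T0 = T0, L = L)
}
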