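# Independent oracles, deliberately written without the graph machinery.

# Holm stepdown: compare the i-th smallest p-value with alpha/(m - i + 1).
holm_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  rej <- integer(0)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) rej <- c(rej, ord[i]) else break
  }
  names(p)[rej]
}

# Lehmann-Romano stepdown for k-FWER: thresholds k*alpha/m for the first k
# positions and k*alpha/(m + k - i) beyond.
lehmann_romano_oracle <- function(p, k, alpha) {
  m <- length(p)
  ord <- order(p)
  thr <- ifelse(seq_len(m) <= k, k * alpha / m,
                k * alpha / (m + k - seq_len(m)))
  rej <- integer(0)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= thr[i]) rej <- c(rej, ord[i]) else break
  }
  names(p)[rej]
}

# Closed-testing adjusted p-values for the weighted Bonferroni local tests:
# the local p-value of H_J is min_j p_j / w_j(J) and the adjusted value of
# H_j is the maximum over all J containing j, capped at 1.
closed_testing_adjusted <- function(graph, p) {
  m <- length(graph$names)
  adj <- stats::setNames(rep(0, m), graph$names)
  for (mask in seq_len(2^m - 1L)) {
    J <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
    wJ <- intersection_weights(graph, J)
    pj <- p[graph$names[J]]
    ratio <- ifelse(wJ > 0, pj / wJ, Inf)
    local <- min(ratio)
    for (j in graph$names[J]) adj[j] <- max(adj[j], local)
  }
  pmin(adj, 1)
}

# Largest D with D/(D + R) <= gamma by brute enumeration (the ratio is
# increasing in D, so scanning until the first failure is exhaustive).
augmentation_count_oracle <- function(R, gamma) {
  D <- 0L
  d <- 1L
  while (d / (d + R) <= gamma + 1e-12) {
    D <- d
    d <- d + 1L
  }
  D
}

# random p-value vector aligned to a graph
random_pvalues <- function(graph, seed) {
  set.seed(seed)
  stats::setNames(round(stats::runif(length(graph$names)), 6), graph$names)
}
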