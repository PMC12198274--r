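# Independent oracles used to validate the package implementations.

# Brute-force Newman modularity: direct double sum over node pairs.
brute_modularity <- function(W, membership) {
  total <- sum(W) / 2
  s <- rowSums(W)
  q <- 0
  n <- nrow(W)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + W[i, j] - s[i] * s[j] / (2 * total)
      }
    }
  }
  q / (2 * total)
}

# Unweighted local clustering by explicit triangle counting.
binary_clustering_oracle <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) {
      for (b in seq(a + 1, k)) {
        if (A[nb[a], nb[b]] > 0) tri <- tri + 1
      }
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

# Random symmetric 0/1 adjacency with zero diagonal.
random_binary_graph <- function(p, prob = 0.4) {
  A <- matrix(0, p, p)
  A[upper.tri(A)] <- rbinom(p * (p - 1) / 2, 1, prob)
  A + t(A)
}

# Small two-group ground truth over the first `p` items.
small_truth <- function(p = 6, edges = list(c(1, 2, 0.3), c(3, 4, 0.25)),
                        groups = c("A", "B"), moderated_edges = NULL) {
  items <- cprs_items()[seq_len(p)]
  m <- matrix(0, p, p, dimnames = list(items, items))
  for (e in edges) {
    m[e[1], e[2]] <- m[e[2], e[1]] <- e[3]
  }
  symptom_truth(base_pcor = m, moderated_edges = moderated_edges,
                groups = groups)
}

# Ground truth used for recovery studies: 18 items, all planted base edges
# at |pcor| >= 0.25, optional moderation deltas.
recovery_truth <- function(moderated_edges = NULL,
                           groups = default_groups()) {
  items <- cprs_items()
  p <- length(items)
  m <- matrix(0, p, p, dimnames = list(items, items))
  pairs <- list(
    c("closeatt", "susatt"), c("listen", "instruct"), c("org", "avoid"),
    c("lose", "distract"), c("fidget", "seat"), c("run", "motor"),
    c("quiet", "talk"), c("blurt", "turn")
  )
  for (pr in pairs) {
    m[pr[1], pr[2]] <- m[pr[2], pr[1]] <- 0.28
  }
  m["forget", "distract"] <- m["distract", "forget"] <- 0.25
  symptom_truth(base_pcor = m, moderated_edges = moderated_edges,
                groups = groups)
}

recovery_truth_edges <- function() {
  list(
    c("closeatt", "susatt"), c("listen", "instruct"), c("org", "avoid"),
    c("lose", "distract"), c("fidget", "seat"), c("run", "motor"),
    c("quiet", "talk"), c("blurt", "turn"), c("forget", "distract")
  )
}
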