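# Independent brute-force oracles for the network operations, written as
# literal double loops over the linking-rule conditions and set operations
# so they share no code path with the vectorized implementations.

brute_network <- function(corr, params = network_params()) {
  m <- nrow(corr)
  score <- if (params$use_abs) abs(corr) else corr
  topk <- function(i, k) {
    v <- score[i, -i]
    idx <- setdiff(seq_len(m), i)
    idx[order(-v)][seq_len(min(k, m - 1L))]
  }
  adj <- matrix(0L, m, m, dimnames = dimnames(corr))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      c1 <- score[i, j] >= params$t_low &&
        (j %in% topk(i, params$k_low) || i %in% topk(j, params$k_low))
      c2 <- score[i, j] >= params$t_high &&
        (j %in% topk(i, params$k_high) || i %in% topk(j, params$k_high))
      if (c1 || c2) adj[i, j] <- 1L
    }
  }
  adj
}

brute_to <- function(net1, net2) {
  sapply(net1$nodes, function(g) {
    x <- net1$nodes[net1$adjacency[g, ] == 1L]
    y <- net2$nodes[net2$adjacency[g, ] == 1L]
    d <- max(length(x), length(y))
    if (d == 0) NA_real_ else length(intersect(x, y)) / d
  })
}

# random simple undirected graph as a coexpression_network, min degree >= 1
random_net <- function(m, p = 0.15, nodes = sprintf("g%03d", seq_len(m))) {
  repeat {
    adj <- matrix(0L, m, m, dimnames = list(nodes, nodes))
    up <- which(upper.tri(adj))
    adj[up] <- as.integer(stats::runif(length(up)) < p)
    adj <- adj + t(adj)
    if (all(rowSums(adj) >= 1)) return(coexpression_network(adj))
  }
}

# symmetric correlation matrix assembled from hand-set entries
corr_from_pairs <- function(genes, pairs, default = 0) {
  m <- length(genes)
  corr <- matrix(default, m, m, dimnames = list(genes, genes))
  diag(corr) <- 1
  for (p in pairs) {
    corr[p[[1]], p[[2]]] <- corr[p[[2]], p[[1]]] <- p[[3]]
  }
  corr
}

# adjacency from an explicit edge list over named nodes
net_from_edges <- function(nodes, edges) {
  adj <- matrix(0L, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (e in edges) {
    adj[e[1], e[2]] <- adj[e[2], e[1]] <- 1L
  }
  coexpression_network(adj)
}
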