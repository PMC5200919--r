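# Independent oracles used across tests. These deliberately avoid the code
# paths they check: union-find instead of graph traversal, hand-rolled BFS
# instead of igraph, direct summation instead of distribution functions.

# small in-memory genotype dataset from a dosage matrix
toy_dataset <- function(G, y, chrom = "chr1", pos = seq_len(ncol(G))) {
  if (is.null(colnames(G))) colnames(G) <- sprintf("s%03d", seq_len(ncol(G)))
  d <- genotype_dataset(
    G,
    data.frame(sample_id = sprintf("i%04d", seq_len(nrow(G))),
               phenotype = as.integer(y), stringsAsFactors = FALSE),
    data.frame(snp_id = colnames(G), chrom = chrom, pos = pos,
               stringsAsFactors = FALSE))
  d$snps$maf <- pmax(pmin(colMeans(d$geno, na.rm = TRUE) / 2,
                          1 - colMeans(d$geno, na.rm = TRUE) / 2), 1e-3)
  d$snps$call_rate <- 1 - colMeans(is.na(d$geno))
  d
}

# union-find connected components over an edge list of node names
uf_components <- function(nodes, edge_a, edge_b) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(edge_a)) {
    ra <- find(edge_a[i]); rb <- find(edge_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(nodes, find, "")
}

# all-pairs shortest path lengths by repeated BFS over an adjacency list
bfs_distances <- function(adj) {
  nodes <- names(adj)
  d <- matrix(Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (s in nodes) {
    d[s, s] <- 0
    frontier <- s; dist <- 0
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                     nodes[is.finite(d[s, ])])
      dist <- dist + 1
      d[s, nxt] <- dist
      frontier <- nxt
    }
  }
  d
}

# Brandes-style betweenness for small graphs, written against the BFS DAG
brute_betweenness <- function(adj) {
  nodes <- names(adj)
  bc <- setNames(numeric(length(nodes)), nodes)
  for (s in nodes) {
    sigma <- setNames(numeric(length(nodes)), nodes); sigma[s] <- 1
    dist <- setNames(rep(-1, length(nodes)), nodes); dist[s] <- 0
    preds <- setNames(vector("list", length(nodes)), nodes)
    queue <- s; order_seen <- character()
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      order_seen <- c(order_seen, v)
      for (w in adj[[v]]) {
        if (dist[[w]] < 0) { dist[[w]] <- dist[[v]] + 1; queue <- c(queue, w) }
        if (dist[[w]] == dist[[v]] + 1) {
          sigma[[w]] <- sigma[[w]] + sigma[[v]]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- setNames(numeric(length(nodes)), nodes)
    for (w in rev(order_seen)) {
      for (v in preds[[w]])
        delta[[v]] <- delta[[v]] + sigma[[v]] / sigma[[w]] * (1 + delta[[w]])
      if (w != s) bc[[w]] <- bc[[w]] + delta[[w]]
    }
  }
  bc / 2   # undirected: each pair counted twice
}

# adjacency list of an undirected edge list
edge_adj <- function(nodes, edge_a, edge_b) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(edge_a)) {
    adj[[edge_a[i]]] <- c(adj[[edge_a[i]]], edge_b[i])
    adj[[edge_b[i]]] <- c(adj[[edge_b[i]]], edge_a[i])
  }
  adj
}

# exact sampler of the discrete zeta (power-law) distribution
rzeta_exact <- function(n, alpha, kmax = 1e5) {
  pm <- (1:kmax)^(-alpha)
  sample.int(kmax, n, replace = TRUE, prob = pm / sum(pm))
}

# Newman-Girvan modularity evaluated directly from the formula
modularity_direct <- function(edge_a, edge_b, membership) {
  m <- length(edge_a)
  within <- sum(membership[edge_a] == membership[edge_b])
  deg <- table(c(edge_a, edge_b))
  dc <- tapply(as.numeric(deg), membership[names(deg)], sum)
  within / m - sum((dc / (2 * m))^2)
}
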