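cand_df <- function(a, b, p = 0.01)
  data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b),
             supporting_pairs = 1L, min_p = p, stringsAsFactors = FALSE)

test_that("network edges are the candidate/PPI intersection", {
  cand <- cand_df(c("A", "B"), c("B", "C"))
  ppi <- data.frame(gene_a = "A", gene_b = "B")
  g <- build_network(cand, ppi)
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))   # C kept isolated
  expect_equal(igraph::degree(g)[["C"]], 0)

  g0 <- build_network(cand, data.frame(gene_a = character(),
                                       gene_b = character()))
  expect_equal(igraph::ecount(g0), 0)

  # random instance vs brute-force pair-set intersection
  set.seed(91)
  genes <- sprintf("g%02d", 1:15)
  rnd_pairs <- function(k) {
    m <- t(replicate(k, sort(sample(genes, 2))))
    unique(data.frame(gene_a = m[, 1], gene_b = m[, 2],
                      stringsAsFactors = FALSE))
  }
  cd <- rnd_pairs(50); cd$supporting_pairs <- 1L; cd$min_p <- 0.01
  pp <- rnd_pairs(50)
  gr <- build_network(cd, pp)
  got <- apply(igraph::as_edgelist(gr), 1, function(e)
    paste(sort(e), collapse = "-"))
  want <- intersect(paste(cd$gene_a, cd$gene_b, sep = "-"),
                    paste(pp$gene_a, pp$gene_b, sep = "-"))
  expect_setequal(got, want)
})

test_that("largest component selection matches a union-find oracle", {
  # two components, sizes 5 and 3
  cand <- cand_df(c("a", "b", "c", "d", "x", "y"),
                  c("b", "c", "d", "e", "y", "z"))
  ppi <- cand[, c("gene_a", "gene_b")]
  g <- build_network(cand, ppi)
  lc <- largest_component(g)
  expect_setequal(igraph::V(lc)$name, c("a", "b", "c", "d", "e"))
  census <- attr(lc, "component_census")
  expect_equal(as.integer(names(census)), c(3L, 5L))

  # connected graph -> identity
  gc <- build_network(cand_df(c("a", "b"), c("b", "c")),
                      data.frame(gene_a = c("a", "b"), gene_b = c("b", "c")))
  expect_equal(igraph::vcount(largest_component(gc)), 3)

  # random sparse graph: component census equals union-find
  set.seed(92)
  nodes <- sprintf("n%03d", 1:200)
  ea <- sample(nodes, 120, replace = TRUE)
  eb <- sample(nodes, 120, replace = TRUE)
  keep <- ea != eb
  cd <- unique(cand_df(ea[keep], eb[keep]))
  gr <- build_network(cd, cd[, 1:2])
  comp <- igraph::components(gr)
  roots <- uf_components(igraph::V(gr)$name, cd$gene_a, cd$gene_b)
  expect_equal(sort(as.integer(table(comp$membership))),
               sort(as.integer(table(roots))))
})

test_that("topology statistics match hand values and BFS oracles", {
  path3 <- build_network(cand_df(c("A", "B"), c("B", "C")),
                         data.frame(gene_a = c("A", "B"),
                                    gene_b = c("B", "C")))
  ts <- topology_stats(path3)
  expect_equal(ts$nodes$betweenness[ts$nodes$gene == "B"], 1)
  expect_equal(ts$nodes$degree[ts$nodes$gene == "B"], 2)
  expect_equal(ts$graph$diameter, 2)

  tri <- build_network(cand_df(c("A", "A", "B"), c("B", "C", "C")),
                       data.frame(gene_a = c("A", "A", "B"),
                                  gene_b = c("B", "C", "C")))
  tt <- topology_stats(tri)
  expect_equal(tt$nodes$clustering, rep(1, 3))
  expect_equal(tt$graph$diameter, 1)

  # 30-node random graph vs oracles
  set.seed(93)
  nodes <- sprintf("v%02d", 1:30)
  ea <- sample(nodes, 60, replace = TRUE)
  eb <- sample(nodes, 60, replace = TRUE)
  keep <- ea != eb
  cd <- unique(cand_df(ea[keep], eb[keep]))
  g <- build_network(cd, cd[, 1:2])
  st <- topology_stats(g)
  adj <- edge_adj(igraph::V(g)$name,
                  igraph::as_edgelist(g)[, 1], igraph::as_edgelist(g)[, 2])
  # degrees
  expect_equal(st$nodes$degree,
               unname(lengths(adj)[st$nodes$gene]))
  # diameter: largest finite BFS distance
  dm <- bfs_distances(adj)
  expect_equal(st$graph$diameter, max(dm[is.finite(dm)]))
  # betweenness
  bb <- brute_betweenness(adj)
  expect_equal(st$nodes$betweenness, unname(bb[st$nodes$gene]),
               tolerance = 1e-9)
  # clustering: triangle count over neighbour pairs
  cc_or <- vapply(st$nodes$gene, function(v) {
    nb <- adj[[v]]
    if (length(nb) < 2) return(0)
    pairs <- combn(nb, 2)
    closed <- sum(apply(pairs, 2, function(pr) pr[2] %in% adj[[pr[1]]]))
    closed / ncol(pairs)
  }, 0)
  expect_equal(st$nodes$clustering, unname(cc_or), tolerance = 1e-12)
})

test_that("power-law fitting is deterministic and rejects misfits", {
  set.seed(94)
  k <- rzeta_exact(300, 2.5)
  f1 <- fit_power_law(k, n_boot = 200, seed = 7)
  f2 <- fit_power_law(k, n_boot = 200, seed = 7)
  expect_identical(f1$p_value, f2$p_value)
  expect_gt(f1$alpha, 1)
  expect_true(f1$ks_D >= 0 && f1$ks_D <= 1)
  expect_error(fit_power_law(rep(3L, 50)), "equal")
  expect_error(fit_power_law(1:5), "at least 10")
  # asymptotic mode returns a valid probability
  fa <- fit_power_law(k, method = "asymptotic")
  expect_true(fa$p_value >= 0 && fa$p_value <= 1)
})

test_that("Poisson hub tails match direct summation and are monotone", {
  cand <- cand_df(c("A", "A", "A", "B"), c("B", "C", "D", "C"))
  g <- build_network(cand, cand[, 1:2])
  h <- hub_test(g)
  lambda <- 2 * igraph::ecount(g) / igraph::vcount(g)
  # independent high-precision summation of the complement
  for (i in seq_len(nrow(h))) {
    k <- h$degree[i]
    tail <- 1 - sum(exp(-lambda) * lambda^(0:(k - 1)) /
                      factorial(0:(k - 1)))
    if (k == 0) tail <- 1
    expect_equal(h$p_raw[i], tail, tolerance = 1e-12)
  }
  expect_true(all(h$p_adjusted <= 1))
  expect_equal(h$p_adjusted, pmin(1, h$p_raw * igraph::vcount(g)))
  # p_raw non-increasing in degree at fixed lambda
  ord <- order(h$degree)
  expect_true(all(diff(h$p_raw[ord]) <= 1e-15))
  # isolated node has p_raw = 1
  cand2 <- rbind(cand, cand_df("E", "F"))
  g2 <- build_network(cand2, cand[, 1:2])   # E-F lacks PPI -> degree 0
  h2 <- hub_test(g2)
  expect_equal(h2$p_raw[h2$gene == "E"], 1)
})

test_that("modularity decomposition recovers planted cliques exactly", {
  clique_edges <- function(v) {
    m <- t(combn(v, 2))
    data.frame(gene_a = m[, 1], gene_b = m[, 2], stringsAsFactors = FALSE)
  }
  a <- sprintf("a%d", 1:5); b <- sprintf("b%d", 1:5)
  el <- rbind(clique_edges(a), clique_edges(b),
              data.frame(gene_a = "a5", gene_b = "b1"))
  el$supporting_pairs <- 1L; el$min_p <- 0.01
  g <- build_network(el, el[, 1:2])
  mp <- decompose_modules(g)
  expect_equal(nrow(mp$modules), 2)
  expect_length(unique(mp$assignment[a]), 1)
  expect_length(unique(mp$assignment[b]), 1)
  expect_false(mp$assignment[[a[1]]] == mp$assignment[[b[1]]])

  # reported Q equals the direct Newman-Girvan formula
  qd <- modularity_direct(el$gene_a, el$gene_b, mp$assignment)
  expect_equal(mp$modularity_q, qd, tolerance = 1e-12)

  # ... and is the maximum over every partition into at most 3 blocks
  nodes <- igraph::V(g)$name
  deg <- table(c(el$gene_a, el$gene_b))[nodes]
  ea <- match(el$gene_a, nodes); eb <- match(el$gene_b, nodes)
  m <- nrow(el)
  best <- -Inf
  for (code in 0:(3^9 - 1)) {      # first node fixed in block 1
    lab <- c(1L, (code %/% 3^(0:8)) %% 3 + 1L)
    within <- sum(lab[ea] == lab[eb])
    dc <- c(sum(deg[lab == 1L]), sum(deg[lab == 2L]), sum(deg[lab == 3L]))
    q <- within / m - sum((dc / (2 * m))^2)
    if (q > best) best <- q
  }
  expect_equal(mp$modularity_q, best, tolerance = 1e-12)

  # single clique stays one module; edgeless graph is all singletons
  g1 <- build_network(cbind(clique_edges(a), supporting_pairs = 1L,
                            min_p = 0.01), clique_edges(a))
  expect_equal(nrow(decompose_modules(g1)$modules), 1)
  ge <- build_network(cbind(clique_edges(a), supporting_pairs = 1L,
                            min_p = 0.01),
                      data.frame(gene_a = character(),
                                 gene_b = character()))
  mpe <- decompose_modules(ge)
  expect_equal(nrow(mpe$modules), 5)
  expect_equal(mpe$modularity_q, 0)
})
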