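#' Build the PPI-supported epistatic gene network
#'
#' The edge set is the intersection (as unordered pairs) of the epistatic
#' gene-pair candidates and the PPI edge table: an edge needs both
#' statistical interaction evidence and an experimentally recorded
#' protein-protein interaction. Candidate genes whose every candidate pair
#' lacks PPI support stay in the graph as isolated nodes, so the component
#' census reflects them.
#'
#' @param candidates Gene-pair candidates from [pairs_to_genes()].
#' @param ppi PPI edge table with columns `gene_a`, `gene_b`.
#' @return An undirected simple `igraph` graph; edges carry
#'   `supporting_pairs` and `min_p`.
#' @export
build_network <- function(candidates, ppi) {
  canon <- function(df) {
    if (nrow(df) == 0) return(character())
    paste(pmin(df$gene_a, df$gene_b), pmax(df$gene_a, df$gene_b),
          sep = "\r")
  }
  ck <- canon(candidates)
  pk <- unique(canon(ppi))
  keep <- ck %in% pk
  edges <- candidates[keep, , drop = FALSE]
  nodes <- sort(unique(c(candidates$gene_a, candidates$gene_b)))
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b", "supporting_pairs", "min_p")],
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  stopifnot(igraph::is_simple(g))
  g
}

#' Extract the largest connected component
#'
#' Returns the induced subgraph on the largest component; size ties are
#' broken toward the component containing the lexicographically smallest
#' gene id. The full component size census is attached as the
#' `"component_census"` attribute (a table of component sizes).
#'
#' @param net An `igraph` network (e.g. from [build_network()]).
#' @return The induced subgraph, with the census attribute.
#' @export
largest_component <- function(net) {
  if (igraph::vcount(net) == 0) {
    warning("empty graph")
    return(net)
  }
  comp <- igraph::components(net)
  best_size <- max(comp$csize)
  cand <- which(comp$csize == best_size)
  if (length(cand) > 1) {
    firsts <- vapply(cand, function(ci)
      min(igraph::V(net)$name[comp$membership == ci]), "")
    cand <- cand[which.min(match(firsts, sort(firsts)))]
  }
  sub <- igraph::induced_subgraph(net, which(comp$membership == cand[1]))
  attr(sub, "component_census") <- table(comp$csize)
  sub
}

#' Topology summary of a gene network
#'
#' Per node: degree, (unweighted shortest-path) betweenness centrality and
#' the local clustering coefficient (0 for nodes of degree < 2). Per
#' graph: diameter (largest finite eccentricity), edge density and the
#' degree histogram.
#'
#' @param net A non-empty `igraph` network.
#' @return List with `nodes` (data frame) and `graph` (list with
#'   `diameter`, `density`, `degree_hist`).
#' @export
topology_stats <- function(net) {
  if (igraph::vcount(net) == 0) stop("empty graph")
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, directed = FALSE)
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  nodes <- data.frame(gene = igraph::V(net)$name, degree = as.integer(deg),
                      betweenness = as.numeric(btw),
                      clustering = as.numeric(cc),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  diam <- if (igraph::ecount(net) == 0) 0 else
    igraph::diameter(net, unconnected = TRUE)
  list(nodes = nodes,
       graph = list(diameter = diam,
                    density = igraph::edge_density(net),
                    degree_hist = table(deg)))
}

# Hurwitz zeta H(alpha, m) = sum_{j>=0} (m+j)^(-alpha), vectorised over m;
# direct sum of the first 15 terms plus an Euler-Maclaurin tail
.hurwitz_zeta <- function(alpha, m) {
  J <- 15L
  direct <- rowSums(outer(m, 0:(J - 1L), `+`)^(-alpha))
  M <- m + J
  direct + M^(1 - alpha) / (alpha - 1) + 0.5 * M^(-alpha) +
    alpha / 12 * M^(-alpha - 1) -
    alpha * (alpha + 1) * (alpha + 2) / 720 * M^(-alpha - 3)
}

# discrete power-law CDF F(k) = 1 - H(alpha, k+1)/H(alpha, xmin)
.plaw_cdf <- function(k, alpha, xmin) {
  1 - .hurwitz_zeta(alpha, k + 1) / .hurwitz_zeta(alpha, xmin)
}

# discrete maximum-likelihood scaling exponent: maximises
# -alpha * sum(log k) - n * log H(alpha, xmin); the continuous
# approximation 1 + n / sum(log(k / (xmin - 0.5))) is only used to centre
# the search bracket (it is strongly biased toward small alpha when
# xmin = 1, so it cannot serve as the estimate itself)
.plaw_alpha <- function(k, xmin) {
  slk <- sum(log(k))
  n <- length(k)
  nll <- function(a) a * slk + n * log(.hurwitz_zeta(a, xmin))
  stats::optimize(nll, c(1 + 1e-6, 25))$minimum
}

# KS sup-distance between the empirical tail CDF and the fitted discrete
# power law, evaluated at the jump points of the empirical CDF
.plaw_ks <- function(k, alpha, xmin) {
  ku <- sort(unique(k))
  S <- cumsum(tabulate(match(k, ku), length(ku))) / length(k)
  Fk <- .plaw_cdf(ku, alpha, xmin)
  Fk_left <- .plaw_cdf(ku - 1, alpha, xmin)
  S_left <- c(0, S[-length(S)])
  max(abs(S - Fk), abs(S_left - Fk_left))
}

# sample n draws from the fitted discrete power law: CDF-table inversion up
# to kmax, analytic tail inversion (H(alpha,k) ~ k^(1-alpha)/(alpha-1))
# beyond it
.plaw_sample <- function(n, alpha, xmin, kmax = 1e5L) {
  H0 <- .hurwitz_zeta(alpha, xmin)
  kmax <- as.integer(min(kmax, max(1000, xmin + 10)))
  ks <- xmin:kmax
  pmf <- ks^(-alpha) / H0
  cdf <- cumsum(pmf)
  u <- runif(n)
  pos <- findInterval(u, cdf) + 1L
  out <- numeric(n)
  over <- pos > length(ks)
  out[!over] <- ks[pos[!over]]
  if (any(over)) {
    # invert P(K >= k) = H(alpha,k)/H0 ~ k^(1-alpha)/((alpha-1) H0)
    tail_u <- pmax(1 - u[over], 1e-300)
    out[over] <- pmax(kmax + 1,
                      round(((alpha - 1) * H0 * tail_u)^(1 / (1 - alpha))))
  }
  out
}

#' Fit a discrete power law to a degree sequence and test its fit
#'
#' Estimates the scaling exponent of \eqn{p(k) \propto k^{-\alpha}},
#' \eqn{k \ge x_{min}}, with the continuous-approximation maximum
#' likelihood estimator \eqn{\hat\alpha = 1 + n / \sum_i \ln(k_i /
#' (x_{min} - 0.5))}, measures goodness of fit with the Kolmogorov-Smirnov
#' sup-distance between the empirical and fitted CDFs, and computes a
#' p-value either by a seeded parametric bootstrap (default: the fraction
#' of `n_boot` synthetic degree sequences drawn from the fitted law whose
#' refitted KS distance exceeds the observed one; a high p-value means the
#' power law is not rejected) or from the asymptotic KS tail. Optionally
#' selects `xmin` by minimising the KS distance (Clauset-style) via
#' `select_xmin = TRUE`.
#'
#' @param degrees Integer degree sequence; values below `xmin` are ignored,
#'   at least 10 must remain.
#' @param xmin Smallest degree included in the fit.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed for the bootstrap.
#' @param method `"bootstrap"` or `"asymptotic"`.
#' @param select_xmin If `TRUE`, `xmin` is chosen among observed degree
#'   values to minimise the KS distance before the final fit.
#' @return A `power_law_fit` list: `alpha`, `xmin`, `ks_D`, `p_value`,
#'   `n_tail`, `method`.
#' @export
fit_power_law <- function(degrees, xmin = 1L, n_boot = 1000L, seed = 1L,
                          method = c("bootstrap", "asymptotic"),
                          select_xmin = FALSE) {
  method <- match.arg(method)
  degrees <- degrees[!is.na(degrees)]
  if (select_xmin) {
    cand <- sort(unique(degrees[degrees >= 1]))
    cand <- cand[vapply(cand, function(x) sum(degrees >= x) >= 10, TRUE)]
    if (length(cand)) {
      ds <- vapply(cand, function(x) {
        kk <- degrees[degrees >= x]
        .plaw_ks(kk, .plaw_alpha(kk, x), x)
      }, 0)
      xmin <- cand[which.min(ds)]
    }
  }
  k <- degrees[degrees >= xmin]
  n <- length(k)
  if (n < 10) stop("need at least 10 degrees >= xmin")
  if (length(unique(k)) == 1)
    stop("all degrees equal; the power-law MLE is undefined")
  alpha <- .plaw_alpha(k, xmin)
  D <- .plaw_ks(k, alpha, xmin)
  if (method == "bootstrap") {
    set.seed(as.integer(seed))
    Db <- vapply(seq_len(n_boot), function(b) {
      kb <- .plaw_sample(n, alpha, xmin)
      .plaw_ks(kb, .plaw_alpha(kb, xmin), xmin)
    }, 0)
    p <- mean(Db >= D)
  } else {
    # asymptotic KS tail: 2 * sum (-1)^(j-1) exp(-2 j^2 n D^2)
    j <- 1:100
    p <- min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * n * D^2))))
  }
  structure(list(alpha = alpha, xmin = as.integer(xmin), ks_D = D,
                 p_value = p, n_tail = n, method = method),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "power_law_fit: alpha = %.3f (xmin = %d, n = %d), KS D = %.4f, P = %.4g (%s)\n",
    x$alpha, x$xmin, x$n_tail, x$ks_D, x$p_value, x$method))
  invisible(x)
}

#' Poisson test for network hub genes
#'
#' Under a homogeneous random-graph null the degree of a node is
#' approximately Poisson with mean \eqn{\lambda = 2E/V}, the mean degree of
#' the graph under test. For each node the upper tail
#' \eqn{P(X \ge \mathrm{degree})} is computed and Bonferroni-corrected over
#' the V nodes; hubs are nodes with adjusted P < 0.05.
#'
#' @param net An `igraph` network with at least 2 nodes.
#' @return Data frame `gene`, `degree`, `lambda`, `p_raw`, `p_adjusted`,
#'   `is_hub`, sorted by increasing `p_raw`.
#' @export
hub_test <- function(net) {
  V <- igraph::vcount(net)
  if (V < 2) stop("hub testing needs at least 2 nodes")
  lambda <- 2 * igraph::ecount(net) / V
  deg <- igraph::degree(net)
  p_raw <- ppois(deg - 1, lambda, lower.tail = FALSE)
  out <- data.frame(gene = igraph::V(net)$name, degree = as.integer(deg),
                    lambda = lambda, p_raw = as.numeric(p_raw),
                    p_adjusted = pmin(1, p_raw * V),
                    stringsAsFactors = FALSE)
  out$is_hub <- out$p_adjusted < 0.05
  out <- out[order(out$p_raw, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decompose a network into modules by modularity maximisation
#'
#' Partitions the node set with Newman-style modularity optimisation:
#' fast-greedy agglomeration by default, with the leading-eigenvector
#' spectral method as an alternative. Module ids are contiguous from 1 in
#' order of first appearance along the vertex order, which makes the
#' labelling deterministic. Reports the Newman-Girvan modularity
#' \eqn{Q = \sum_c (e_c/m - (d_c/2m)^2)} of the returned partition and a
#' topology row (nodes, edges, diameter) per module.
#'
#' @param net An `igraph` network (typically a connected component).
#' @param algorithm `"fast_greedy"` or `"leading_eigenvector"`.
#' @return A `module_partition` list: `assignment` (named module ids),
#'   `modularity_q`, `modules` (data frame `module`, `n_nodes`, `n_edges`,
#'   `diameter`).
#' @export
decompose_modules <- function(net,
                              algorithm = c("fast_greedy",
                                            "leading_eigenvector")) {
  algorithm <- match.arg(algorithm)
  if (igraph::vcount(net) == 0) stop("empty graph")
  if (igraph::ecount(net) == 0) {
    memb <- seq_len(igraph::vcount(net))
    names(memb) <- igraph::V(net)$name
    q <- 0
  } else {
    if (algorithm == "fast_greedy") {
      comm <- igraph::cluster_fast_greedy(net)
      # cut the agglomeration dendrogram at its own modularity maximum:
      # membership() can sit one merge short of the recorded optimum
      k_best <- which.max(comm$modularity)
      raw <- igraph::cut_at(comm, no = igraph::vcount(net) - (k_best - 1L))
    } else {
      comm <- igraph::cluster_leading_eigen(net)
      raw <- igraph::membership(comm)
    }
    # relabel contiguously by first appearance for determinism
    memb <- match(raw, unique(raw))
    names(memb) <- igraph::V(net)$name
    q <- igraph::modularity(net, memb)
  }
  rows <- lapply(sort(unique(memb)), function(m) {
    sub <- igraph::induced_subgraph(net, which(memb == m))
    data.frame(module = m, n_nodes = igraph::vcount(sub),
               n_edges = igraph::ecount(sub),
               diameter = if (igraph::ecount(sub) == 0) 0 else
                 igraph::diameter(sub, unconnected = TRUE))
  })
  structure(list(assignment = memb, modularity_q = q,
                 modules = do.call(rbind, rows)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules over %d nodes, Q = %.4f\n",
              nrow(x$modules), length(x$assignment), x$modularity_q))
  print(x$modules, row.names = FALSE)
  invisible(x)
}

#' Gene lists of a module partition
#'
#' @param partition A `module_partition` from [decompose_modules()].
#' @return Named list of gene-id vectors, one per module (`M1`, `M2`, ...).
#' @export
module_gene_lists <- function(partition) {
  stopifnot(inherits(partition, "module_partition"))
  split(names(partition$assignment),
        paste0("M", partition$assignment))[
          paste0("M", sort(unique(partition$assignment)))]
}
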