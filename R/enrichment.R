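#' Depth of an ontology term
#'
#' Depth is 1 plus the length of the shortest directed `is_a` path from the
#' term to its namespace root, so the root itself has depth 1 and a term
#' with parents at depths 2 and 5 has depth 3 (minimum-distance rule).
#'
#' @param onto A [go_ontology()].
#' @param term Term identifier.
#' @return Integer depth >= 1.
#' @export
term_depth <- function(onto, term) {
  stopifnot(inherits(onto, "go_ontology"))
  d <- .term_depth_table(onto)
  if (!term %in% names(d)) stop("unknown term: ", term)
  if (is.na(d[[term]])) stop("term does not reach its root: ", term)
  d[[term]]
}

# ancestors (transitive is_a closure, excluding the term itself)
.term_ancestors <- function(onto, term) {
  anc <- character()
  frontier <- onto$parents[[term]]
  while (length(frontier)) {
    frontier <- setdiff(frontier, anc)
    anc <- c(anc, frontier)
    frontier <- unique(unlist(onto$parents[frontier], use.names = FALSE))
  }
  unique(anc)
}

#' Propagate gene annotations up the ontology
#'
#' True-path propagation: a gene annotated to a term is counted for every
#' ancestor of that term along `is_a` edges. The operation is idempotent.
#' Annotations to terms absent from the ontology are dropped with a
#' warning.
#'
#' @param annotations Data frame `gene_id`, `term_id`.
#' @param onto A [go_ontology()].
#' @return The propagated (deduplicated, sorted) annotation table.
#' @export
propagate_annotations <- function(annotations, onto) {
  stopifnot(inherits(onto, "go_ontology"))
  known <- annotations$term_id %in% onto$terms$term_id
  if (any(!known)) {
    warning("dropping annotations to unknown terms: ",
            paste(unique(annotations$term_id[!known]), collapse = ", "))
    annotations <- annotations[known, , drop = FALSE]
  }
  terms <- unique(annotations$term_id)
  closure <- lapply(terms, function(t) c(t, .term_ancestors(onto, t)))
  names(closure) <- terms
  reps <- lengths(closure)[annotations$term_id]
  out <- data.frame(
    gene_id = rep(annotations$gene_id, reps),
    term_id = unlist(closure[annotations$term_id], use.names = FALSE),
    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$gene_id, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric GO enrichment of one module
#'
#' Over-representation analysis of a module's gene list against a
#' background universe. For every term with at least one module gene after
#' true-path propagation, the one-sided hypergeometric tail
#' \eqn{P(X \ge k)} is computed with `N` = background size, `K` = genes
#' annotated to the term or its descendants, `n` = module size,
#' `k` = overlap. Bonferroni correction is over the terms tested for this
#' module, and the report keeps only terms of ontology depth at least
#' `min_depth` (default 4), sorted by raw p-value. Modules smaller than
#' `min_module_size` return an empty table flagged by the `"skipped"`
#' attribute. `ease = TRUE` applies the DAVID/EASE penalised variant,
#' which removes one overlapping gene (\eqn{P(X \ge k - 1)} on the reduced
#' table).
#'
#' @param module_genes Character vector of module genes (must be a subset
#'   of `background`).
#' @param annotations Data frame `gene_id`, `term_id` (direct annotations;
#'   propagation is applied internally).
#' @param onto A [go_ontology()].
#' @param background Background gene universe; defaults to all genes in
#'   the annotation table.
#' @param min_depth Minimum reported term depth.
#' @param min_module_size Smallest module analysed (inclusive).
#' @param ease Use the EASE-penalised score instead of the plain tail.
#' @return Data frame with columns `term_id`, `category`, `name`, `depth`,
#'   `k_overlap`, `n_module`, `K_annotated`, `N_background`, `p_raw`,
#'   `p_adjusted`.
#' @export
enrich_module <- function(module_genes, annotations, onto,
                          background = NULL, min_depth = 4L,
                          min_module_size = 10L, ease = FALSE) {
  stopifnot(inherits(onto, "go_ontology"))
  if (is.null(background)) background <- unique(annotations$gene_id)
  if (length(background) == 0) stop("empty background gene universe")
  if (!all(module_genes %in% background))
    stop("module genes must be a subset of the background")
  empty <- data.frame(term_id = character(), category = character(),
                      name = character(), depth = integer(),
                      k_overlap = integer(), n_module = integer(),
                      K_annotated = integer(), N_background = integer(),
                      p_raw = numeric(), p_adjusted = numeric())
  if (length(module_genes) < min_module_size) {
    attr(empty, "skipped") <- sprintf(
      "module of %d genes below the %d-gene analysis threshold",
      length(module_genes), min_module_size)
    return(empty)
  }
  prop <- propagate_annotations(annotations, onto)
  prop <- prop[prop$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(module_genes)
  by_term <- split(prop$gene_id, prop$term_id)
  k <- vapply(by_term, function(g) sum(g %in% module_genes), 0L)
  K <- lengths(by_term)
  tested <- k >= 1L
  if (!any(tested)) {
    attr(empty, "skipped") <- "no annotated module genes"
    return(empty)
  }
  k <- k[tested]; K <- K[tested]
  # EASE subtracts one gene from the overlap, so its score is the tail at
  # k - 1 (P(X >= k - 1)); the plain score is P(X >= k)
  p_raw <- phyper(if (ease) k - 2 else k - 1, K, N - K, n,
                  lower.tail = FALSE)
  n_tested <- length(k)
  depth_tab <- .term_depth_table(onto)
  out <- data.frame(
    term_id = names(k),
    category = onto$terms$namespace[match(names(k), onto$terms$term_id)],
    name = onto$terms$name[match(names(k), onto$terms$term_id)],
    depth = as.integer(depth_tab[names(k)]),
    k_overlap = as.integer(k), n_module = n,
    K_annotated = as.integer(K), N_background = N,
    p_raw = as.numeric(p_raw),
    p_adjusted = pmin(1, p_raw * n_tested),
    stringsAsFactors = FALSE)
  out <- out[out$depth >= min_depth, , drop = FALSE]
  out <- out[order(out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_terms_tested") <- n_tested
  out
}

#' GO enrichment across all modules of a partition
#'
#' Convenience wrapper applying [enrich_module()] to every module of a
#' [decompose_modules()] partition and binding the results with a `module`
#' column.
#'
#' @inheritParams enrich_module
#' @param partition A `module_partition`.
#' @return Data frame of enrichment rows with a leading `module` column;
#'   skipped modules are recorded in the `"skipped_modules"` attribute.
#' @export
enrich_modules <- function(partition, annotations, onto, background = NULL,
                           min_depth = 4L, min_module_size = 10L,
                           ease = FALSE) {
  lists <- module_gene_lists(partition)
  skipped <- character()
  rows <- lapply(names(lists), function(m) {
    r <- enrich_module(lists[[m]], annotations, onto, background,
                       min_depth, min_module_size, ease)
    if (!is.null(attr(r, "skipped"))) {
      skipped <<- c(skipped, setNames(attr(r, "skipped"), m))
      return(NULL)
    }
    if (nrow(r) == 0) return(NULL)
    cbind(module = m, r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(module = character(), term_id = character(),
                      category = character(), name = character(),
                      depth = integer(), k_overlap = integer(),
                      n_module = integer(), K_annotated = integer(),
                      N_background = integer(), p_raw = numeric(),
                      p_adjusted = numeric())
  rownames(out) <- NULL
  attr(out, "skipped_modules") <- skipped
  out
}
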