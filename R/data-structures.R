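#' Construct a genotype dataset
#'
#' Bundles an additive minor-allele dosage matrix (samples x SNPs, entries
#' 0/1/2 counting minor alleles, `NA` for missing) with its sample table and
#' SNP metadata. This is the container every QC and association stage works
#' on.
#'
#' @param geno Numeric/integer matrix, samples in rows, SNPs in columns,
#'   entries in `{0, 1, 2, NA}`.
#' @param samples Data frame with columns `sample_id` and `phenotype`
#'   (0 = control, 1 = case).
#' @param snps Data frame with at least `snp_id`, `chrom` and `pos`
#'   (1-based position). Optional columns used downstream: `gene_id`,
#'   `minor_allele`, `major_allele`, `maf`, `call_rate`.
#' @return An object of class `genotype_dataset`: a list with elements
#'   `geno`, `samples`, `snps`.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
#' d <- genotype_dataset(
#'   g,
#'   data.frame(sample_id = c("s1", "s2"), phenotype = c(1L, 0L)),
#'   data.frame(snp_id = c("a", "b"), chrom = "chr1", pos = c(100L, 200L))
#' )
#' d
#' @export
genotype_dataset <- function(geno, samples, snps) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (!all(c("sample_id", "phenotype") %in% names(samples)))
    stop("'samples' needs columns sample_id and phenotype")
  if (!all(c("snp_id", "chrom", "pos") %in% names(snps)))
    stop("'snps' needs columns snp_id, chrom and pos")
  if (nrow(geno) != nrow(samples))
    stop("row count of 'geno' does not match 'samples'")
  if (ncol(geno) != nrow(snps))
    stop("column count of 'geno' does not match 'snps'")
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (!all(samples$phenotype %in% c(0L, 1L)))
    stop("phenotype must be coded 0 (control) / 1 (case)")
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample ids")
  if (anyDuplicated(snps$snp_id)) stop("duplicated SNP ids")
  rownames(geno) <- samples$sample_id
  colnames(geno) <- snps$snp_id
  rownames(samples) <- NULL
  rownames(snps) <- NULL
  structure(list(geno = geno, samples = samples, snps = snps),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  nc <- sum(x$samples$phenotype == 1L)
  cat(sprintf(
    "genotype_dataset: %d samples (%d cases / %d controls) x %d SNPs, %.2f%% missing\n",
    nrow(x$geno), nc, nrow(x$geno) - nc, ncol(x$geno),
    100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Number of samples / SNPs in a genotype dataset
#' @param data A [genotype_dataset()].
#' @return Integer count.
#' @export
n_samples <- function(data) nrow(data$geno)

#' @rdname n_samples
#' @export
n_snps <- function(data) ncol(data$geno)

# observed minor-allele frequency and call rate per SNP; maf is folded so it
# never exceeds 0.5 even if imputation shifted the allele balance
.snp_maf <- function(geno) {
  f <- colMeans(geno, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

.snp_call_rate <- function(geno) 1 - colMeans(is.na(geno))

#' Specify the kernel of the SNP-set test
#'
#' @param kind Kernel family: `"linear"` (weighted linear kernel
#'   \eqn{K(z_i, z_{i'}) = \sum_j w_j z_{ij} z_{i'j}}, the default),
#'   `"gaussian"` or `"ibs"` (identity-by-state).
#' @param weight_scheme Per-SNP weights: `"beta"` uses the squared
#'   Beta(`a1`, `a2`) density evaluated at the minor allele frequency (the
#'   SKAT convention, default Beta(1, 25)), `"flat"` uses weight 1 for every
#'   SNP.
#' @param a1,a2 Positive shape parameters of the beta weighting density.
#' @param gaussian_rho Positive bandwidth of the Gaussian kernel. When
#'   `NULL` it defaults to the number of SNPs in the set at kernel build
#'   time.
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(kind = c("linear", "gaussian", "ibs"),
                        weight_scheme = c("beta", "flat"),
                        a1 = 1, a2 = 25, gaussian_rho = NULL) {
  kind <- match.arg(kind)
  weight_scheme <- match.arg(weight_scheme)
  if (a1 <= 0 || a2 <= 0) stop("beta weight parameters must be positive")
  if (!is.null(gaussian_rho) && gaussian_rho <= 0)
    stop("gaussian_rho must be positive")
  structure(list(kind = kind, weight_scheme = weight_scheme,
                 a1 = a1, a2 = a2, gaussian_rho = gaussian_rho),
            class = "kernel_spec")
}

#' Construct a gene ontology graph
#'
#' A rooted directed acyclic graph of terms connected by `is_a` edges
#' (child to parent), one root per namespace. Term depth is defined as
#' 1 + the length of the shortest directed path to the namespace root, so
#' roots sit at depth 1.
#'
#' @param terms Data frame with columns `term_id`, `name`, `namespace`
#'   (one of `"BP"`, `"CC"`, `"MF"`).
#' @param edges Data frame with columns `child`, `parent` listing `is_a`
#'   relations.
#' @return An object of class `go_ontology` with elements `terms`, `edges`,
#'   `roots` (named by namespace), `parents` and `children` adjacency lists.
#' @export
go_ontology <- function(terms, edges) {
  stopifnot(all(c("term_id", "name", "namespace") %in% names(terms)))
  if (nrow(edges) > 0) stopifnot(all(c("child", "parent") %in% names(edges)))
  if (anyDuplicated(terms$term_id)) stop("duplicated term ids")
  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$term_id)
  if (length(unknown))
    stop("edges reference unknown terms: ", paste(unknown, collapse = ", "))
  parents <- split(edges$parent, factor(edges$child, levels = terms$term_id))
  children <- split(edges$child, factor(edges$parent, levels = terms$term_id))
  has_parent <- lengths(parents) > 0
  roots_id <- terms$term_id[!has_parent]
  ns <- terms$namespace[match(roots_id, terms$term_id)]
  if (anyDuplicated(ns))
    stop("more than one root term in a namespace")
  roots <- setNames(roots_id, ns)
  onto <- structure(list(terms = terms, edges = edges, roots = roots,
                         parents = parents, children = children),
                    class = "go_ontology")
  # Kahn topological check: every term must be reachable and the edge set
  # acyclic, otherwise depths are ill-defined
  d <- .term_depth_table(onto)
  if (anyNA(d))
    stop("ontology has terms that do not reach their namespace root: ",
         paste(names(d)[is.na(d)], collapse = ", "))
  indeg <- lengths(parents)
  q <- names(indeg)[indeg == 0]
  seen <- 0L
  indeg_w <- indeg
  while (length(q)) {
    t <- q[[1]]; q <- q[-1]; seen <- seen + 1L
    for (ch in children[[t]]) {
      indeg_w[[ch]] <- indeg_w[[ch]] - 1L
      if (indeg_w[[ch]] == 0L) q <- c(q, ch)
    }
  }
  if (seen != nrow(terms)) stop("ontology graph contains a cycle")
  onto
}

#' @export
print.go_ontology <- function(x, ...) {
  cat(sprintf("go_ontology: %d terms, %d is_a edges, roots: %s\n",
              nrow(x$terms), nrow(x$edges),
              paste(sprintf("%s=%s", names(x$roots), x$roots),
                    collapse = ", ")))
  invisible(x)
}

# breadth-first depths (root = 1) for all terms; NA for unreachable terms
.term_depth_table <- function(onto) {
  depth <- setNames(rep(NA_integer_, nrow(onto$terms)), onto$terms$term_id)
  frontier <- unname(onto$roots)
  depth[frontier] <- 1L
  d <- 1L
  while (length(frontier)) {
    nxt <- unique(unlist(onto$children[frontier], use.names = FALSE))
    nxt <- nxt[!is.na(nxt)]
    nxt <- nxt[is.na(depth[nxt])]
    depth[nxt] <- d + 1L
    frontier <- nxt
    d <- d + 1L
  }
  depth
}
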