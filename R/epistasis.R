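# Newton/IRLS fit of a logistic model; small fixed design, used for the
# 4-parameter interaction model where calling glm() per pair would dominate
# the scan's runtime. Tolerance 1e-8 on the step, at most `maxit` iterations.
.logistic_irls <- function(X, y, tol = 1e-8, maxit = 50L) {
  b <- numeric(ncol(X))
  b[1] <- qlogis(min(max(mean(y), 1e-8), 1 - 1e-8))
  A <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    A <- crossprod(X * sqrt(w))
    g <- crossprod(X, y - mu)
    delta <- tryCatch(solve(A, g), error = function(e) NULL)
    if (is.null(delta))
      return(list(coef = b, cov = NULL, converged = FALSE, iter = it))
    b <- b + drop(delta)
    if (max(abs(delta)) < tol)
      return(list(coef = b, cov = solve(A), converged = TRUE, iter = it))
  }
  list(coef = b, cov = solve(A), converged = FALSE, iter = maxit)
}

#' Pairwise SNP-by-SNP interaction test
#'
#' Fits the full logistic interaction model
#' \deqn{\mathrm{logit}\,P(y=1) = b_0 + b_1 g_1 + b_2 g_2 + b_3 g_1 g_2}
#' by maximum likelihood (Newton/IRLS, PLINK epistasis semantics) and
#' returns the two-sided Wald test of \eqn{b_3 = 0}. Pairs whose dosage or
#' product column is constant are reported not testable; fits with any
#' coefficient beyond 15 in absolute value are flagged as quasi-separated
#' and excluded downstream, as are non-converged fits.
#'
#' @param g1,g2 Complete dosage vectors of the two SNPs.
#' @param y Binary phenotype with both classes.
#' @param snp_a,snp_b SNP identifiers; stored in canonical (lexicographic)
#'   order.
#' @return One-row data frame `snp_a`, `snp_b`, `beta_int`, `se`, `p`,
#'   `n_used`, `status` (`"ok"`, `"not_testable"`, `"separation"`,
#'   `"no_convergence"`).
#' @export
interaction_test <- function(g1, g2, y, snp_a = "snp_a", snp_b = "snp_b") {
  if (length(g1) != length(g2) || length(g1) != length(y))
    stop("g1, g2 and y must have the same length")
  if (anyNA(g1) || anyNA(g2)) stop("interaction test expects imputed dosages")
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) < 2)
    stop("phenotype must be binary with both classes present")
  if (snp_a > snp_b) { tmp <- g1; g1 <- g2; g2 <- tmp
                       tmp <- snp_a; snp_a <- snp_b; snp_b <- tmp }
  row <- function(beta, se, p, status)
    data.frame(snp_a = snp_a, snp_b = snp_b, beta_int = beta, se = se,
               p = p, n_used = length(y), status = status,
               stringsAsFactors = FALSE)
  x3 <- g1 * g2
  if (var(g1) == 0 || var(g2) == 0 || var(x3) == 0)
    return(row(NA_real_, NA_real_, NA_real_, "not_testable"))
  X <- cbind(1, g1, g2, x3)
  fit <- .logistic_irls(X, y)
  if (!fit$converged || is.null(fit$cov))
    return(row(NA_real_, NA_real_, NA_real_, "no_convergence"))
  if (any(abs(fit$coef) > 15))
    return(row(fit$coef[4], NA_real_, NA_real_, "separation"))
  se <- sqrt(fit$cov[4, 4])
  z <- fit$coef[4] / se
  row(fit$coef[4], se, 2 * pnorm(-abs(z)), "ok")
}

#' Exhaustive epistasis scan over significant pathways
#'
#' Tests every unordered pair of distinct SNPs in the union of the supplied
#' SNP sets (within- and cross-pathway alike) with [interaction_test()],
#' and retains pairs with `p < alpha`. No multiple-testing correction is
#' applied at this stage by design: the nominal screen is later tightened
#' by the PPI-support requirement of [build_network()]. The scan is
#' order-independent: the retained set does not depend on the SNP input
#' order.
#'
#' @param data An imputed [genotype_dataset()].
#' @param sig_sets SNP sets of the significant pathways (subset of
#'   [make_snp_sets()] output).
#' @param alpha Retention threshold on the nominal interaction p-value.
#' @return Data frame of retained pairs (`snp_a`, `snp_b`, `beta_int`,
#'   `se`, `p`, `n_used`, `status`), sorted by `p`. Attributes
#'   `n_pairs_tested`, `n_retained` and `n_not_testable` carry the scan
#'   log.
#' @export
scan_significant_pathways <- function(data, sig_sets, alpha = 0.05) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (length(sig_sets) < 1) stop("no significant pathway SNP sets supplied")
  if (anyNA(data$geno)) stop("epistasis scan expects imputed dosages")
  snps <- sort(unique(unlist(lapply(sig_sets, `[[`, "snp_ids"),
                             use.names = FALSE)))
  if (length(snps) < 2)
    stop("the union of the significant pathways holds fewer than 2 SNPs")
  miss <- setdiff(snps, colnames(data$geno))
  if (length(miss))
    stop("SNP set references SNPs absent from the dataset: ",
         paste(head(miss, 3), collapse = ", "))
  y <- data$samples$phenotype
  G <- data$geno[, snps, drop = FALSE]
  idx <- combn(length(snps), 2)
  rows <- vector("list", ncol(idx))
  n_nt <- 0L
  for (k in seq_len(ncol(idx))) {
    i <- idx[1, k]; j <- idx[2, k]
    r <- interaction_test(G[, i], G[, j], y, snps[i], snps[j])
    if (r$status != "ok") n_nt <- n_nt + 1L
    rows[[k]] <- r
  }
  all_res <- do.call(rbind, rows)
  keep <- all_res$status == "ok" & all_res$p < alpha
  out <- all_res[keep, , drop = FALSE]
  out <- out[order(out$p, out$snp_a, out$snp_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_pairs_tested") <- ncol(idx)
  attr(out, "n_retained") <- nrow(out)
  attr(out, "n_not_testable") <- n_nt
  out
}

#' Translate retained SNP pairs into candidate gene pairs
#'
#' Each retained SNP pair expands to every (gene of A) x (gene of B)
#' combination under the SNP-to-gene map; same-gene combinations are
#' discarded (network edges connect distinct genes) and duplicates collapse
#' into one candidate with `supporting_pairs` incremented and the smallest
#' interaction p-value tracked. SNPs absent from the map are dropped and
#' listed in the `"unmapped_snps"` attribute.
#'
#' @param results Retained pairs from [scan_significant_pathways()].
#' @param snp_gene_map Data frame `snp_id`, `gene_id`.
#' @return Data frame `gene_a`, `gene_b` (canonical order),
#'   `supporting_pairs`, `min_p`, sorted by gene pair.
#' @export
pairs_to_genes <- function(results, snp_gene_map) {
  gmap <- split(snp_gene_map$gene_id, snp_gene_map$snp_id)
  unmapped <- character()
  acc <- vector("list", nrow(results))
  for (k in seq_len(nrow(results))) {
    ga <- gmap[[results$snp_a[k]]]
    gb <- gmap[[results$snp_b[k]]]
    if (is.null(ga)) unmapped <- c(unmapped, results$snp_a[k])
    if (is.null(gb)) unmapped <- c(unmapped, results$snp_b[k])
    if (is.null(ga) || is.null(gb)) next
    grid <- expand.grid(a = ga, b = gb, stringsAsFactors = FALSE)
    grid <- grid[grid$a != grid$b, , drop = FALSE]
    if (!nrow(grid)) next
    acc[[k]] <- data.frame(gene_a = pmin(grid$a, grid$b),
                           gene_b = pmax(grid$a, grid$b),
                           p = results$p[k], stringsAsFactors = FALSE)
  }
  expanded <- do.call(rbind, acc)
  if (is.null(expanded) || nrow(expanded) == 0) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      supporting_pairs = integer(), min_p = numeric())
    attr(out, "unmapped_snps") <- unique(unmapped)
    return(out)
  }
  key <- paste(expanded$gene_a, expanded$gene_b, sep = "\r")
  agg_n <- tapply(expanded$p, key, length)
  agg_p <- tapply(expanded$p, key, min)
  parts <- do.call(rbind, strsplit(names(agg_n), "\r", fixed = TRUE))
  out <- data.frame(gene_a = parts[, 1], gene_b = parts[, 2],
                    supporting_pairs = as.integer(agg_n),
                    min_p = as.numeric(agg_p), stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped_snps") <- unique(unmapped)
  out
}
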