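#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts
#' against the p^2 / 2pq / q^2 proportions expected from the estimated
#' allele frequency. Monomorphic input returns P = 1 by convention. An
#' exact (Wigginton-style) test conditioning on the observed allele counts
#' is available via `method = "exact"`.
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts (either homozygote
#'   may be listed first; the test is symmetric).
#' @param method `"chisq"` (default) or `"exact"`.
#' @return P value in \[0, 1\].
#' @examples
#' hwe_test(25, 50, 25)   # exact HWE proportions -> 1
#' hwe_test(100, 0, 100)  # gross departure -> ~0
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("chisq", "exact")) {
  method <- match.arg(method)
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotyped individual")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  if (method == "chisq") {
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    x2 <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
    return(pchisq(x2, df = 1, lower.tail = FALSE))
  }
  .hwe_exact(n_AA, n_Aa, n_aa)
}

# exact test: enumerate heterozygote counts compatible with the observed
# allele counts, sum probabilities <= that of the observed table
.hwe_exact <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_AA + n_Aa        # rarer-or-not does not matter: symmetric
  het <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  logp <- vapply(het, function(h) {
    aa <- (n_a - h) / 2
    bb <- n - aa - h
    lchoose(n, aa) + lchoose(n - aa, h) + h * log(2) -
      lchoose(2 * n, n_a)
  }, 0)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, het)]
  min(1, sum(pr[pr <= obs + 1e-12]))
}

# vectorised chi-square HWE over dosage columns (rows = individuals)
.hwe_pvalues <- function(geno) {
  n0 <- colSums(geno == 0L, na.rm = TRUE)
  n1 <- colSums(geno == 1L, na.rm = TRUE)
  n2 <- colSums(geno == 2L, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * pmax(n, 1))
  q <- 1 - p
  out <- rep(1, ncol(geno))
  poly <- n > 0 & p > 0 & p < 1
  e0 <- n * q^2; e1 <- 2 * n * p * q; e2 <- n * p^2
  x2 <- (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2
  out[poly] <- pchisq(x2[poly], df = 1, lower.tail = FALSE)
  out
}

#' Quality-control filtering of a genotype dataset
#'
#' Applies the standard GWAS screens in a fixed, logged order:
#' (1) remove SNPs with missing rate >= `snp_miss_max`;
#' (2) remove samples with missing rate >= `sample_miss_max` over the
#' remaining SNPs; (3) recompute allele frequencies and remove SNPs with
#' MAF <= `maf_min`; (4) remove SNPs whose Hardy-Weinberg P value in the
#' control group is <= `hwe_alpha`. Defaults keep SNPs with missing rate
#' < 5%, individuals with missing rate < 5%, MAF > 0.01 and control-group
#' HWE P > 1e-4.
#'
#' @param data A [genotype_dataset()].
#' @param snp_miss_max,sample_miss_max Missing-rate thresholds (exclusive
#'   survival bounds).
#' @param maf_min Minimum minor allele frequency (exclusive).
#' @param hwe_alpha HWE screening level (exclusive).
#' @return A list with `data` (the filtered dataset, with refreshed `maf`
#'   and `call_rate` columns) and `report` (a `qc_report` with per-filter
#'   counts, removed identifiers and the thresholds used).
#' @export
filter_dataset <- function(data, snp_miss_max = 0.05, sample_miss_max = 0.05,
                           maf_min = 0.01, hwe_alpha = 1e-4) {
  stopifnot(inherits(data, "genotype_dataset"))
  g <- data$geno
  if (nrow(g) == 0 || ncol(g) == 0) stop("empty dataset")

  snp_miss <- colMeans(is.na(g))
  rm_miss <- snp_miss >= snp_miss_max
  g <- g[, !rm_miss, drop = FALSE]

  samp_miss <- rowMeans(is.na(g))
  rm_samp <- samp_miss >= sample_miss_max
  g <- g[!rm_samp, , drop = FALSE]
  samples <- data$samples[!rm_samp, , drop = FALSE]

  maf <- .snp_maf(g)
  rm_maf <- is.na(maf) | maf <= maf_min

  is_ctrl <- samples$phenotype == 0L
  if (!any(is_ctrl))
    stop("no controls left; HWE screening needs a control group")
  hwe_p <- .hwe_pvalues(g[is_ctrl, , drop = FALSE])
  rm_hwe <- !rm_maf & hwe_p <= hwe_alpha

  keep <- !(rm_maf | rm_hwe)
  g <- g[, keep, drop = FALSE]
  if (ncol(g) == 0 || nrow(g) == 0)
    stop("all SNPs or all samples removed by QC")

  kept_ids <- colnames(g)
  snps <- data$snps[match(kept_ids, data$snps$snp_id), , drop = FALSE]
  snps$maf <- .snp_maf(g)
  snps$call_rate <- .snp_call_rate(g)
  out <- genotype_dataset(g, samples, snps)

  snp_ids <- data$snps$snp_id
  report <- structure(list(
    thresholds = list(snp_miss_max = snp_miss_max,
                      sample_miss_max = sample_miss_max,
                      maf_min = maf_min, hwe_alpha = hwe_alpha),
    filter_order = c("snp_missingness", "sample_missingness", "maf", "hwe"),
    n_snps_in = ncol(data$geno), n_samples_in = nrow(data$geno),
    n_snps_out = ncol(g), n_samples_out = nrow(g),
    removed = list(
      snp_missingness = snp_ids[rm_miss],
      sample_missingness = data$samples$sample_id[rm_samp],
      maf = snp_ids[!rm_miss][rm_maf],
      hwe = snp_ids[!rm_miss][rm_hwe])), class = "qc_report")
  list(data = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d -> %d SNPs, %d -> %d samples\n",
              x$n_snps_in, x$n_snps_out, x$n_samples_in, x$n_samples_out))
  for (f in x$filter_order)
    cat(sprintf("  removed by %-19s %d\n", paste0(f, ":"),
                length(x$removed[[f]])))
  invisible(x)
}

#' Impute missing genotypes with the per-SNP modal genotype
#'
#' Each missing entry is replaced by the most frequent observed genotype
#' code of that SNP; ties are resolved toward the smaller dosage code.
#' Observed genotypes are never changed.
#'
#' @param data A [genotype_dataset()] (normally after [filter_dataset()]).
#' @return The dataset with no missing entries; `call_rate` keeps the
#'   pre-imputation values for use by [prune_tag_snps()].
#' @export
impute_most_frequent <- function(data) {
  stopifnot(inherits(data, "genotype_dataset"))
  g <- data$geno
  pre_call <- .snp_call_rate(g)
  miss_cols <- which(colSums(is.na(g)) > 0)
  for (j in miss_cols) {
    obs <- g[, j][!is.na(g[, j])]
    if (length(obs) == 0)
      stop("SNP ", colnames(g)[j], " has no observed genotypes")
    counts <- tabulate(obs + 1L, nbins = 3L)
    mode <- which.max(counts) - 1L   # which.max takes the first (lowest) tie
    g[is.na(g[, j]), j] <- mode
  }
  snps <- data$snps
  snps$maf <- .snp_maf(g)
  snps$call_rate <- pre_call
  genotype_dataset(g, data$samples, snps)
}

#' Squared dosage correlation between two SNPs
#'
#' Composite LD measured as the squared Pearson correlation of additive
#' dosage vectors (no phasing needed). Returns 0 when either vector is
#' constant.
#'
#' @param g1,g2 Equal-length dosage vectors without missing values.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("dosage vectors differ in length")
  if (length(g1) < 2) stop("need at least two individuals")
  if (anyNA(g1) || anyNA(g2)) stop("ld_r2 expects imputed (complete) dosages")
  if (var(g1) == 0 || var(g2) == 0) return(0)
  cor(g1, g2)^2
}

#' Moving-window tag-SNP pruning
#'
#' Per chromosome, slides a window of `window` SNPs by `step`; within each
#' window, while any retained pair has r-squared > `r2_max`, one member of
#' the most correlated offending pair is removed. The removal rule is
#' deterministic: drop the SNP with more pre-imputation missingness (lower
#' `call_rate`), break ties by lower MAF, then by later position. A SNP
#' removed in any window stays removed; the output keeps the original SNP
#' order.
#'
#' @param data A [genotype_dataset()], imputed and sorted by
#'   (chromosome, position).
#' @param window Window size in SNPs (>= 2).
#' @param step Step length in SNPs.
#' @param r2_max Pairwise r-squared cutoff above which SNPs are thinned.
#' @return A list with `data` (tag SNPs only) and `removed` (character
#'   vector of pruned SNP ids).
#' @export
prune_tag_snps <- function(data, window = 50L, step = 5L, r2_max = 0.8) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (window < 2) stop("window must span at least 2 SNPs")
  if (step < 1) stop("step must be >= 1")
  if (anyNA(data$geno)) stop("prune_tag_snps expects imputed dosages")
  snps <- data$snps
  ord <- order(snps$chrom, snps$pos)
  if (!identical(ord, seq_len(nrow(snps))))
    stop("SNPs must be sorted by (chrom, pos); reorder the dataset first")

  removed <- rep(FALSE, nrow(snps))
  pos <- snps$pos; maf <- snps$maf
  call_rate <- if (!is.null(snps$call_rate)) snps$call_rate else
    rep(1, nrow(snps))

  for (chr in unique(snps$chrom)) {
    idx <- which(snps$chrom == chr)
    len <- length(idx)
    starts <- seq(1L, len, by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, len)]
      repeat {
        kept <- win[!removed[win]]
        if (length(kept) < 2) break
        cc <- suppressWarnings(cor(data$geno[, kept, drop = FALSE]))
        cc[is.na(cc)] <- 0
        r2 <- cc^2
        diag(r2) <- 0
        if (max(r2) <= r2_max) break
        hit <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        a <- kept[hit[1]]; b <- kept[hit[2]]
        # decide which of the offending pair goes
        drop_a <-
          if (call_rate[a] != call_rate[b]) call_rate[a] < call_rate[b]
          else if (maf[a] != maf[b]) maf[a] < maf[b]
          else pos[a] > pos[b]
        removed[if (drop_a) a else b] <- TRUE
      }
      if (s + window - 1L >= len) break
    }
  }
  keep <- !removed
  out <- genotype_dataset(data$geno[, keep, drop = FALSE], data$samples,
                          snps[keep, , drop = FALSE])
  list(data = out, removed = snps$snp_id[removed])
}

#' Map SNPs to genes by position with flanking regions
#'
#' A SNP at 1-based position p maps to a gene with 0-based half-open body
#' \[s, e) iff `s + 1 - flank <= p <= e + flank`, i.e. it falls inside the
#' gene or within `flank` bp of either end (default 5 kb). A SNP may map to
#' several genes; unmapped SNPs are recorded in the `"unmapped"` attribute.
#'
#' @param snps SNP table with `snp_id`, `chrom`, `pos` (1-based).
#' @param genes Gene table with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param flank Flank length in bp on each side.
#' @return Data frame `snp_id`, `gene_id` (one row per mapping), sorted;
#'   attribute `"unmapped"` holds the SNP ids that hit no gene.
#' @export
map_snps_to_genes <- function(snps, genes, flank = 5000L) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (nrow(snps) == 0 || nrow(genes) == 0) {
    out <- data.frame(snp_id = character(), gene_id = character())
    attr(out, "unmapped") <- snps$snp_id
    return(out)
  }
  q <- GenomicRanges::GRanges(snps$chrom,
                              IRanges::IRanges(snps$pos, snps$pos))
  s <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$start + 1L - flank),
                     genes$end + flank))
  hits <- GenomicRanges::findOverlaps(q, s)
  out <- data.frame(snp_id = snps$snp_id[S4Vectors::queryHits(hits)],
                    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
                    stringsAsFactors = FALSE)
  out <- unique(out[order(out$snp_id, out$gene_id), , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "unmapped") <- setdiff(snps$snp_id, out$snp_id)
  out
}
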