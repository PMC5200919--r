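#' Per-SNP weights for the kernel
#'
#' Under the beta scheme (the SKAT convention) the weight of SNP j is the
#' squared Beta(a1, a2) density evaluated at its minor allele frequency,
#' which with the default Beta(1, 25) strongly up-weights rare variants.
#' The flat scheme gives every SNP weight 1.
#'
#' @param mafs Minor allele frequencies in (0, 0.5].
#' @param spec A [kernel_spec()].
#' @return Numeric weight vector, same length as `mafs`.
#' @export
compute_weights <- function(mafs, spec = kernel_spec()) {
  if (any(mafs <= 0 | mafs > 0.5))
    stop("minor allele frequencies must lie in (0, 0.5]")
  switch(spec$weight_scheme,
         flat = rep(1, length(mafs)),
         beta = dbeta(mafs, spec$a1, spec$a2)^2)
}

#' Build the similarity kernel of a SNP set
#'
#' * linear: \eqn{K = Z \mathrm{diag}(w) Z^T}, i.e.
#'   \eqn{K(z_i, z_{i'}) = \sum_j w_j z_{ij} z_{i'j}} (the default, and the
#'   form the score test is usually written for);
#' * gaussian: \eqn{K(i,i') = \exp(-\sum_j (z_{ij}-z_{i'j})^2 / \rho)}
#'   (unweighted; `rho` defaults to the number of SNPs);
#' * ibs: average identity-by-state sharing,
#'   \eqn{\sum_j w_j (2 - |z_{ij}-z_{i'j}|) / (2 \sum_j w_j)}.
#'
#' @param Z Dosage matrix (samples x SNPs), no missing values.
#' @param weights Per-SNP weights from [compute_weights()].
#' @param spec A [kernel_spec()].
#' @return Symmetric positive semi-definite kernel matrix (samples x
#'   samples).
#' @export
build_kernel <- function(Z, weights, spec = kernel_spec()) {
  Z <- as.matrix(Z)
  if (ncol(Z) != length(weights))
    stop("number of SNP columns does not match the weight vector")
  if (anyNA(Z)) stop("kernel construction expects imputed dosages")
  switch(spec$kind,
    linear = tcrossprod(sweep(Z, 2, sqrt(weights), `*`)),
    gaussian = {
      rho <- if (is.null(spec$gaussian_rho)) ncol(Z) else spec$gaussian_rho
      unname(exp(-as.matrix(stats::dist(Z))^2 / rho))
    },
    ibs = {
      m <- as.matrix(stats::dist(sweep(Z, 2, weights, `*`),
                                 method = "manhattan"))
      unname((2 * sum(weights) - m) / (2 * sum(weights)))
    })
}

#' Fit the null logistic model
#'
#' Maximum-likelihood logistic regression of the phenotype on the
#' covariates only (intercept-only by default), giving the fitted null
#' probabilities used by the score test. With no covariates the MLE is the
#' case fraction for every subject.
#'
#' @param y Binary phenotype vector with both classes present.
#' @param covariates Optional numeric covariate matrix (no intercept
#'   column).
#' @return A `null_model` list with `mu0` (fitted probabilities), `X` (the
#'   null design matrix) and `y`.
#' @export
fit_null_logistic <- function(y, covariates = NULL) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("phenotype must be binary 0/1")
  if (length(unique(y)) < 2)
    stop("phenotype has a single class; the null model is degenerate")
  n <- length(y)
  if (is.null(covariates)) {
    X <- matrix(1, n, 1)
    mu0 <- rep(mean(y), n)
  } else {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows do not match phenotype")
    X <- cbind(1, covariates)
    fit <- glm.fit(X, y, family = binomial())
    if (!fit$converged)
      stop("null logistic fit did not converge")
    if (any(abs(fit$coefficients) > 15))
      stop("apparent separation on the null covariates")
    mu0 <- fit$fitted.values
  }
  structure(list(mu0 = mu0, X = X, y = y), class = "null_model")
}

#' Score statistic and null eigenvalues of the kernel test
#'
#' Computes the variance-component score statistic
#' \eqn{Q = (y - \hat\mu_0)^T K (y - \hat\mu_0) / 2} and the weights of its
#' null chi-square mixture: the eigenvalues of
#' \eqn{\tfrac{1}{2} P_0^{1/2} K P_0^{1/2}}, where
#' \eqn{P_0 = D - DX(X^T D X)^{-1} X^T D} and
#' \eqn{D = \mathrm{diag}(\hat\mu_0(1-\hat\mu_0))}. Small negative
#' eigenvalues (above `-1e-8` times the largest) are clipped to zero;
#' anything more negative signals a broken projection and raises an error.
#'
#' @param y Binary phenotype vector.
#' @param mu0 Fitted null probabilities (from [fit_null_logistic()]).
#' @param K Symmetric kernel matrix.
#' @param X Null design matrix (defaults to intercept-only).
#' @return List with `q` (the statistic) and `lambda` (non-negative
#'   eigenvalues, zeros dropped).
#' @export
score_statistic <- function(y, mu0, K, X = NULL) {
  n <- length(y)
  K <- as.matrix(K)
  if (!isSymmetric(K, tol = 1e-8)) stop("kernel matrix is not symmetric")
  if (is.null(X)) X <- matrix(1, n, 1)
  r <- y - mu0
  q <- drop(crossprod(r, K %*% r)) / 2
  d <- mu0 * (1 - mu0)
  XtDX <- crossprod(X, d * X)
  DX <- d * X
  P0 <- diag(d) - DX %*% solve(XtDX, t(DX))
  ep <- eigen((P0 + t(P0)) / 2, symmetric = TRUE)
  vals <- pmax(ep$values, 0)
  P0h <- ep$vectors %*% (sqrt(vals) * t(ep$vectors))
  M <- P0h %*% K %*% P0h / 2
  lam <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  list(q = q, lambda = .clip_eigenvalues(lam))
}

.clip_eigenvalues <- function(lam) {
  mx <- max(lam, 0)
  if (any(lam < -1e-8 * max(mx, 1)))
    stop("projected kernel has a substantially negative eigenvalue")
  lam <- pmax(lam, 0)
  lam[lam > 1e-12 * max(mx, 1)]
}

# low-rank route for the linear kernel: the non-zero eigenvalues of
# (1/2) P0^(1/2) G G' P0^(1/2) equal those of (1/2) G' P0 G (p x p)
.score_lowrank <- function(y, mu0, G, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  r <- y - mu0
  q <- sum(drop(crossprod(G, r))^2) / 2
  d <- mu0 * (1 - mu0)
  GtDG <- crossprod(G, d * G)
  GtDX <- crossprod(G, d * X)
  XtDX <- crossprod(X, d * X)
  A <- (GtDG - GtDX %*% solve(XtDX, t(GtDX))) / 2
  lam <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  list(q = q, lambda = .clip_eigenvalues(lam))
}

#' Tail probability of a weighted chi-square mixture
#'
#' P-value of the score statistic against its null law
#' \eqn{\sum_k \lambda_k \chi^2_{1,k}}. The default (`"davies"`) inverts
#' the characteristic function of the quadratic form numerically
#' (Davies/Imhof family, adaptive quadrature, target accuracy 1e-6 or
#' better); if the integration fails or returns a value outside \[0, 1\]
#' the moment-matched non-central chi-square approximation of Liu type
#' (`"moment"`) is used instead and recorded in the `"method_used"`
#' attribute.
#'
#' @param q_stat Observed statistic (non-negative).
#' @param eigenvalues Non-negative mixture weights; all-zero returns 1.
#' @param method `"davies"` or `"moment"`.
#' @return P value in \[0, 1\] with attribute `method_used`.
#' @export
pvalue_mixture_chisq <- function(q_stat, eigenvalues,
                                 method = c("davies", "moment")) {
  method <- match.arg(method)
  if (any(eigenvalues < -1e-10)) stop("eigenvalues must be non-negative")
  lam <- eigenvalues[eigenvalues > 0]
  if (length(lam) == 0)
    return(structure(1, method_used = "degenerate"))
  if (method == "davies") {
    p <- tryCatch(.qf_pvalue_cf(q_stat, lam), error = function(e) NA_real_)
    if (!is.na(p) && p > 1e-12 && p <= 1)
      return(structure(min(max(p, 0), 1), method_used = "davies"))
    # fall through to the moment approximation on failure / underflow
  }
  structure(.qf_pvalue_liu(q_stat, lam), method_used = "moment")
}

# characteristic-function inversion (Imhof's integral representation):
# P(Q > q) = 1/2 + (1/pi) * Int_0^Inf sin(theta(u)) / (u * rho(u)) du
# The integrand oscillates with slow polynomial decay, so adaptive
# quadrature is tried from tight to loose tolerance; the loosest still
# bounds the error near 1e-6, the accuracy this family of methods targets.
.qf_pvalue_cf <- function(q, lam) {
  f <- function(u) {
    out <- numeric(length(u))
    zero <- u == 0
    out[zero] <- 0.5 * (sum(lam) - q)
    uu <- u[!zero]
    if (length(uu)) {
      lu <- outer(lam, uu)
      th <- 0.5 * colSums(atan(lu)) - 0.5 * q * uu
      lr <- 0.25 * colSums(log1p(lu^2))
      out[!zero] <- sin(th) / (uu * exp(lr))
    }
    out
  }
  for (tol in c(1e-8, 1e-6)) {
    I <- tryCatch(
      integrate(f, 0, Inf, rel.tol = tol, abs.tol = tol * 1e-2,
                subdivisions = 5000L, stop.on.error = TRUE)$value,
      error = function(e) NULL)
    if (!is.null(I)) return(0.5 + I / pi)
  }
  stop("characteristic-function inversion did not converge")
}

# moment-matched (Liu-Tang-Zhang style) non-central chi-square tail
.qf_pvalue_liu <- function(q, lam) {
  c1 <- sum(lam); c2 <- sum(lam^2); c3 <- sum(lam^3); c4 <- sum(lam^4)
  s1 <- c3 / c2^(3 / 2)
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / sqrt(s2)
    delta <- 0
    l <- 1 / s2
  }
  mu_x <- l + delta
  sigma_x <- sqrt(2) * a
  tstar <- (q - c1) / sqrt(2 * c2)
  min(max(pchisq(tstar * sigma_x + mu_x, df = l, ncp = delta,
                 lower.tail = FALSE), 0), 1)
}

#' Bonferroni adjustment of raw p-values
#'
#' `p_adjusted = min(1, p_raw * n_tests)`; significance over the family is
#' claimed when `p_raw * n_tests < alpha`.
#'
#' @param p_raw Raw p-values.
#' @param n_tests Number of tests in the family.
#' @return Adjusted p-values, capped at 1.
#' @examples
#' bonferroni_adjust(7.57e-8, 276)  # 2.09e-5
#' @export
bonferroni_adjust <- function(p_raw, n_tests) pmin(1, p_raw * n_tests)

#' Assemble pathway SNP sets
#'
#' Joins pathway gene sets with a SNP-to-gene map into the units of kernel
#' testing. Pathways that pick up no SNPs are dropped (recorded in the
#' `"dropped"` attribute).
#'
#' @param pathways Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param snp_gene_map Data frame `snp_id`, `gene_id` from
#'   [map_snps_to_genes()].
#' @return List of `pathway_snp_set` lists (`pathway_id`, `snp_ids`,
#'   `gene_ids`).
#' @export
make_snp_sets <- function(pathways, snp_gene_map) {
  sets <- lapply(names(pathways), function(pid) {
    genes <- pathways[[pid]]
    snps <- sort(unique(snp_gene_map$snp_id[snp_gene_map$gene_id %in% genes]))
    structure(list(pathway_id = pid, snp_ids = snps, gene_ids = genes),
              class = "pathway_snp_set")
  })
  keep <- vapply(sets, function(s) length(s$snp_ids) > 0, TRUE)
  out <- sets[keep]
  attr(out, "dropped") <- names(pathways)[!keep]
  out
}

#' Pathway-level SNP-set association testing
#'
#' Runs the logistic kernel machine score test for every SNP set: fits the
#' null model once, builds each set's weighted kernel, computes the Q
#' statistic and its chi-square-mixture p-value, and applies Bonferroni
#' control over the `N` sets tested (`p_adjusted = min(1, p_raw * N)`;
#' a set is flagged significant when `p_raw * N < 0.05`). Results are
#' sorted by raw p-value. Sets referencing SNPs absent from the dataset
#' are skipped with an `NA` row.
#'
#' @param data An imputed [genotype_dataset()].
#' @param snp_sets List of SNP sets from [make_snp_sets()].
#' @param spec A [kernel_spec()].
#' @param covariates Optional covariate matrix for the null model.
#' @param method P-value method, see [pvalue_mixture_chisq()].
#' @param alpha Family-wise significance level for the Bonferroni flag.
#' @return Data frame with columns `pathway_id`, `n_snps`, `q_stat`,
#'   `p_raw`, `p_adjusted`, `significant`, sorted by `p_raw`.
#' @export
test_pathways <- function(data, snp_sets, spec = kernel_spec(),
                          covariates = NULL, method = "davies",
                          alpha = 0.05) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (length(snp_sets) < 1) stop("need at least one SNP set")
  if (anyNA(data$geno)) stop("association testing expects imputed dosages")
  nm <- fit_null_logistic(data$samples$phenotype, covariates)
  N <- length(snp_sets)
  maf_all <- setNames(data$snps$maf, data$snps$snp_id)

  rows <- lapply(snp_sets, function(set) {
    miss <- setdiff(set$snp_ids, colnames(data$geno))
    if (length(miss)) {
      warning("skipping ", set$pathway_id, ": unknown SNPs ",
              paste(head(miss, 3), collapse = ", "))
      return(data.frame(pathway_id = set$pathway_id,
                        n_snps = length(set$snp_ids), q_stat = NA_real_,
                        p_raw = NA_real_, stringsAsFactors = FALSE))
    }
    Z <- data$geno[, set$snp_ids, drop = FALSE]
    w <- compute_weights(maf_all[set$snp_ids], spec)
    if (spec$kind == "linear") {
      sc <- .score_lowrank(nm$y, nm$mu0, sweep(Z, 2, sqrt(w), `*`), nm$X)
    } else {
      K <- build_kernel(Z, w, spec)
      sc <- score_statistic(nm$y, nm$mu0, K, nm$X)
    }
    p <- pvalue_mixture_chisq(sc$q, sc$lambda, method)
    data.frame(pathway_id = set$pathway_id, n_snps = ncol(Z),
               q_stat = sc$q, p_raw = as.numeric(p),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- bonferroni_adjust(res$p_raw, N)
  res$significant <- !is.na(res$p_raw) & res$p_raw * N < alpha
  res <- res[order(res$p_raw), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_sets_tested") <- N
  res
}
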