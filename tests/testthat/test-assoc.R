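test_that("kernel weights follow the beta-density convention", {
  expect_equal(compute_weights(c(0.1, 0.3), kernel_spec(weight_scheme = "flat")),
               c(1, 1))
  # closed form at MAF 0.5 under Beta(1, 25): density 25 * 0.5^24
  w <- compute_weights(0.5, kernel_spec())
  expect_equal(w, (25 * 0.5^24)^2)
  # monotone decreasing in MAF for a1 = 1, a2 = 25
  mafs <- seq(0.01, 0.5, by = 0.01)
  expect_true(all(diff(compute_weights(mafs, kernel_spec())) < 0))
  expect_error(compute_weights(c(0.2, 0.6)), "0, 0.5")
  expect_error(compute_weights(0), "0, 0.5")
})

test_that("kernels match elementwise hand evaluation and are PSD", {
  set.seed(71)
  Z <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2)
  w <- c(0.5, 2)
  K <- build_kernel(Z, w, kernel_spec(kind = "linear"))
  # brute-force double loop of the weighted linear kernel
  Kb <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    Kb[i, j] <- sum(w * Z[i, ] * Z[j, ])
  expect_equal(K, Kb)
  expect_true(isSymmetric(K))
  expect_gte(min(eigen(K, symmetric = TRUE)$values), -1e-10)

  # single SNP: outer product of the dosage column
  z1 <- matrix(c(0, 1, 2), 3, 1)
  expect_equal(build_kernel(z1, 1, kernel_spec()), outer(c(0, 1, 2), c(0, 1, 2)))

  # IBS kernel, brute loop
  Kibs <- build_kernel(Z, w, kernel_spec(kind = "ibs"))
  Kib <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    Kib[i, j] <- sum(w * (2 - abs(Z[i, ] - Z[j, ]))) / (2 * sum(w))
  expect_equal(Kibs, Kib)

  # gaussian kernel, brute loop
  Kg <- build_kernel(Z, w, kernel_spec(kind = "gaussian", gaussian_rho = 3))
  Kgb <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    Kgb[i, j] <- exp(-sum((Z[i, ] - Z[j, ])^2) / 3)
  expect_equal(Kg, Kgb)

  # a larger random Gram matrix stays PSD
  Zr <- matrix(rbinom(200, 2, 0.3), 20, 10)
  Kr <- build_kernel(Zr, runif(10), kernel_spec())
  expect_gte(min(eigen(Kr, symmetric = TRUE)$values), -1e-10)
})

test_that("null logistic fit returns the closed-form and IRLS solutions", {
  y <- c(rep(1L, 1926), rep(0L, 2938))
  nm <- fit_null_logistic(y)
  expect_equal(unique(nm$mu0), 1926 / 4864)
  expect_equal(unique(fit_null_logistic(rep(c(0L, 1L), 30))$mu0), 0.5)
  expect_error(fit_null_logistic(rep(1L, 10)), "single class")

  # one binary covariate: compare to an independent IRLS loop
  set.seed(72)
  x <- rbinom(200, 1, 0.5)
  yy <- rbinom(200, 1, plogis(-0.3 + 0.8 * x))
  nm2 <- fit_null_logistic(yy, cbind(x))
  X <- cbind(1, x)
  b <- c(0, 0)
  for (it in 1:50) {
    mu <- plogis(drop(X %*% b))
    W <- mu * (1 - mu)
    b <- b + solve(t(X) %*% (W * X), t(X) %*% (yy - mu))
  }
  expect_equal(nm2$mu0, plogis(drop(X %*% b)), tolerance = 1e-8)
})

test_that("score statistic and eigenvalues match brute-force oracles", {
  set.seed(73)
  for (rep in 1:5) {
    n <- 8; p <- 3
    Z <- matrix(rbinom(n * p, 2, 0.4), n, p)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    w <- runif(p, 0.2, 2)
    K <- build_kernel(Z, w, kernel_spec())
    mu0 <- rep(mean(y), n)
    sc <- score_statistic(y, mu0, K)
    # brute-force quadratic form
    qb <- 0
    for (i in 1:n) for (j in 1:n)
      qb <- qb + (y[i] - mu0[i]) * K[i, j] * (y[j] - mu0[j])
    expect_equal(sc$q, qb / 2, tolerance = 1e-10)
    # dense and low-rank eigenvalue routes agree
    lr <- padnet:::.score_lowrank(y, mu0, sweep(Z, 2, sqrt(w), `*`))
    expect_equal(sc$q, lr$q, tolerance = 1e-10)
    expect_equal(sort(sc$lambda, decreasing = TRUE),
                 sort(lr$lambda, decreasing = TRUE), tolerance = 1e-8)
    # trace identities of the projected kernel
    d <- mu0 * (1 - mu0)
    X <- matrix(1, n, 1)
    P0 <- diag(d) - (d * X) %*% solve(crossprod(X, d * X), t(d * X))
    M <- P0 %*% K / 2
    expect_equal(sum(sc$lambda), sum(diag(M)), tolerance = 1e-10)
    expect_equal(sum(sc$lambda^2), sum(diag(M %*% M)), tolerance = 1e-10)
  }
  # degenerate cases: all-zero residuals, all-zero kernel
  n <- 8
  y <- rep(c(0L, 1L), 4)
  expect_equal(score_statistic(rep(0.5, n), rep(0.5, n), diag(8))$q, 0)
  sc0 <- score_statistic(y, rep(0.5, n), matrix(0, n, n))
  expect_equal(sc0$q, 0)
  expect_length(sc0$lambda, 0)
})

test_that("mixture-chi-square tail matches closed form and Monte Carlo", {
  # single eigenvalue: exact 1-df chi-square survival
  for (q in c(0.5, 3.84, 10, 30))
    expect_equal(as.numeric(pvalue_mixture_chisq(q, 1)),
                 pchisq(q, 1, lower.tail = FALSE), tolerance = 1e-6)
  expect_equal(as.numeric(pvalue_mixture_chisq(5, numeric(0))), 1)
  expect_equal(as.numeric(pvalue_mixture_chisq(5, c(0, 0))), 1)
  # two eigenvalues vs a Monte-Carlo oracle
  set.seed(74)
  draws <- 2 * rchisq(1e6, 1) + rchisq(1e6, 1)
  mc <- mean(draws > 5)
  se <- sqrt(mc * (1 - mc) / 1e6)
  expect_lt(abs(as.numeric(pvalue_mixture_chisq(5, c(2, 1))) - mc), 3 * se)
  # davies and moment agree to the approximation's accuracy
  p_d <- as.numeric(pvalue_mixture_chisq(8, c(3, 2, 1), "davies"))
  p_m <- as.numeric(pvalue_mixture_chisq(8, c(3, 2, 1), "moment"))
  expect_lt(abs(p_d - p_m), 0.01)
})

test_that("zero-weight SNPs do not perturb the statistic or p-value", {
  set.seed(75)
  n <- 60
  Z <- matrix(rbinom(n * 4, 2, 0.3), n, 4)
  noise <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, 0.5)
  if (length(unique(y)) < 2) y[1] <- 1L - y[1]
  mu0 <- rep(mean(y), n)
  w <- c(1, 0.5, 2, 1)
  sc1 <- score_statistic(y, mu0, build_kernel(Z, w, kernel_spec()))
  sc2 <- score_statistic(y, mu0,
                         build_kernel(cbind(Z, noise), c(w, 0), kernel_spec()))
  expect_equal(sc1$q, sc2$q)
  expect_equal(sc1$lambda, sc2$lambda, tolerance = 1e-12)
  expect_equal(as.numeric(pvalue_mixture_chisq(sc1$q, sc1$lambda)),
               as.numeric(pvalue_mixture_chisq(sc2$q, sc2$lambda)))
})

test_that("pathway testing applies Bonferroni control and ordering", {
  set.seed(76)
  n <- 150
  G <- matrix(rbinom(n * 12, 2, 0.3), n, 12)
  colnames(G) <- sprintf("s%03d", 1:12)
  d <- toy_dataset(G, rep(c(1L, 0L), n / 2))
  map <- data.frame(snp_id = colnames(G),
                    gene_id = rep(c("gA", "gB", "gC"), each = 4))
  pw <- list(p1 = "gA", p2 = "gB", p3 = c("gA", "gC"))
  sets <- make_snp_sets(pw, map)
  expect_length(sets, 3)
  expect_setequal(sets[[3]]$snp_ids,
                  map$snp_id[map$gene_id %in% c("gA", "gC")])
  res <- test_pathways(d, sets)
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 3))
  expect_false(is.unsorted(res$p_raw))
  expect_equal(attr(res, "n_sets_tested"), 3L)
  # an unknown-SNP set is skipped with an NA row, others still tested
  bad <- structure(list(pathway_id = "bad", snp_ids = "nope",
                        gene_ids = "gZ"), class = "pathway_snp_set")
  expect_warning(res2 <- test_pathways(d, c(sets, list(bad))), "skipping")
  expect_true(is.na(res2$p_raw[res2$pathway_id == "bad"]))
  expect_equal(sum(!is.na(res2$p_raw)), 3)
})

test_that("Bonferroni arithmetic reproduces the worked adjustment examples", {
  expect_equal(bonferroni_adjust(7.57e-8, 276), 2.09e-5, tolerance = 0.005)
  expect_equal(bonferroni_adjust(3.59e-5, 276), 9.92e-3, tolerance = 0.005)
  expect_equal(bonferroni_adjust(0.5, 276), 1)
})
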