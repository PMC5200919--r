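test_that("gene annotation packs disjoint intervals and is deterministic", {
  cfg1 <- sim_config(n_genes = 1, n_pathways = 1,
                     pathway_size_range = c(1, 1), seed = 5)
  g1 <- generate_gene_annotation(cfg1)
  expect_equal(nrow(g1), 1L)
  expect_true(g1$end > g1$start)

  cfg <- sim_config(n_genes = 100, seed = 9)
  ga <- generate_gene_annotation(cfg)
  gb <- generate_gene_annotation(cfg)
  expect_identical(ga, gb)

  # sweep-line overlap scan per chromosome
  for (chr in unique(ga$chrom)) {
    gi <- ga[ga$chrom == chr, ]
    gi <- gi[order(gi$start), ]
    if (nrow(gi) > 1)
      expect_true(all(gi$start[-1] >= gi$end[-nrow(gi)]))
  }

  tiny <- sim_config(n_genes = 100, chrom_length = 5000, max_chroms = 3,
                     seed = 2)
  expect_error(generate_gene_annotation(tiny), "pack|chromosome")
})

test_that("pathway generation respects sizes, risk declarations and overlap mode", {
  cfg <- sim_config(n_genes = 40, n_pathways = 1,
                    pathway_size_range = c(5, 5), seed = 3)
  pw <- generate_pathways(cfg, generate_gene_annotation(cfg))
  expect_length(pw, 1)
  expect_length(pw[[1]], 5)

  cfg <- sim_config(n_genes = 60, n_pathways = 20,
                    pathway_size_range = c(5, 30),
                    risk_pathways = list(list(id = "pw03", beta = 0.3)),
                    seed = 8)
  genes <- generate_gene_annotation(cfg)
  pw <- generate_pathways(cfg, genes)
  sizes <- lengths(pw)
  expect_true(all(sizes >= 5 & sizes <= 30))
  expect_true("pw03" %in% names(pw))
  expect_true(all(unlist(pw) %in% genes$gene_id))

  cfgd <- sim_config(n_genes = 50, n_pathways = 10,
                     pathway_size_range = c(5, 5), pathway_overlap = FALSE,
                     seed = 4)
  pwd <- generate_pathways(cfgd, generate_gene_annotation(cfgd))
  expect_equal(anyDuplicated(unlist(pwd)), 0L)

  expect_error(sim_config(pathway_size_range = c(9, 5)), "empty")
  expect_error(sim_config(n_genes = 4, pathway_size_range = c(5, 6)),
               "exceed")
})

test_that("config validation rejects malformed planted pairs", {
  expect_error(sim_config(epistatic_pairs = list(
    list(snp_a = "g001_s1", snp_b = "g001_s1", gamma = 1))), "distinct")
  expect_error(sim_config(epistatic_pairs = list(
    list(snp_a = "g001_s1", snp_b = "g001_s2", gamma = 1))),
    "distinct genes")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(missing_rate = 0.6), "missing_rate")
})

test_that("genotype generation honours counts, missingness and determinism", {
  cfg <- sim_config(n_cases = 120, n_controls = 180, n_genes = 10,
                    snps_per_gene = c(2, 4), missing_rate = 0,
                    pathway_size_range = c(3, 5), seed = 21)
  genes <- generate_gene_annotation(cfg)
  pw <- generate_pathways(cfg, genes)
  gt <- generate_genotypes(cfg, genes, pw)
  expect_equal(sum(gt$data$samples$phenotype == 1L), 120L)
  expect_equal(sum(gt$data$samples$phenotype == 0L), 180L)
  expect_false(anyNA(gt$data$geno))

  gt2 <- generate_genotypes(cfg, genes, pw)
  expect_identical(gt$data$geno, gt2$data$geno)
  expect_identical(gt$truth, gt2$truth)

  cfg_m <- sim_config(n_cases = 200, n_controls = 200, n_genes = 10,
                      missing_rate = 0.1, pathway_size_range = c(3, 5),
                      seed = 22)
  genes_m <- generate_gene_annotation(cfg_m)
  gt_m <- generate_genotypes(cfg_m, genes_m,
                             generate_pathways(cfg_m, genes_m))
  expect_gt(mean(is.na(gt_m$data$geno)), 0.07)
  expect_lt(mean(is.na(gt_m$data$geno)), 0.13)

  # truth bookkeeping
  expect_length(intersect(gt$truth$risk_pathway_ids,
                          gt$truth$null_pathway_ids), 0)
  expect_equal(sort(c(gt$truth$risk_pathway_ids,
                      gt$truth$null_pathway_ids)), sort(names(pw)))
})

test_that("null generation leaves case and control allele frequencies equal", {
  cfg <- sim_config(n_cases = 1000, n_controls = 1000, n_genes = 20,
                    snps_per_gene = c(5, 5), missing_rate = 0, seed = 31)
  genes <- generate_gene_annotation(cfg)
  gt <- generate_genotypes(cfg, genes, generate_pathways(cfg, genes))
  y <- gt$data$samples$phenotype
  g <- gt$data$geno
  # two-proportion z-test on allele counts per SNP
  z_p <- apply(g, 2, function(col) {
    p1 <- sum(col[y == 1]) / (2 * sum(y == 1))
    p0 <- sum(col[y == 0]) / (2 * sum(y == 0))
    pp <- (sum(col)) / (2 * length(col))
    se <- sqrt(pp * (1 - pp) * (1 / (2 * sum(y == 1)) + 1 / (2 * sum(y == 0))))
    2 * pnorm(-abs((p1 - p0) / se))
  })
  # nominal calibration leaves ~95% of SNPs non-significant; allow the
  # binomial 3-SE band around that mean for the finite SNP count
  expect_gte(mean(z_p > 0.05), 0.95 - 3 * sqrt(0.05 * 0.95 / length(z_p)))
})

test_that("planted main effects shift risk-SNP frequencies toward cases", {
  cfg <- sim_config(n_cases = 1000, n_controls = 1000, n_genes = 20,
                    snps_per_gene = c(2, 2), n_pathways = 4,
                    pathway_size_range = c(5, 5), pathway_overlap = FALSE,
                    missing_rate = 0,
                    risk_pathways = list(list(id = "pw01", beta = 0.4)),
                    seed = 33)
  genes <- generate_gene_annotation(cfg)
  pw <- generate_pathways(cfg, genes)
  gt <- generate_genotypes(cfg, genes, pw)
  y <- gt$data$samples$phenotype
  risk_snps <- gt$data$snps$snp_id[gt$data$snps$gene_id %in% pw$pw01]
  expect_length(risk_snps, 10)
  diffs <- vapply(risk_snps, function(s) {
    col <- gt$data$geno[, s]
    mean(col[y == 1]) / 2 - mean(col[y == 0]) / 2
  }, 0)
  expect_gte(sum(diffs > 0), 8)
})

test_that("PPI generation guarantees planted pairs and calibrated background", {
  cfg <- sim_config(n_genes = 100, snps_per_gene = c(2, 2),
                    n_cases = 50, n_controls = 50, missing_rate = 0,
                    ppi_background_prob = 0,
                    epistatic_pairs = list(
                      list(snp_a = "g001_s1", snp_b = "g002_s1", gamma = 1),
                      list(snp_a = "g003_s1", snp_b = "g004_s1", gamma = 1),
                      list(snp_a = "g005_s1", snp_b = "g006_s1", gamma = 1)),
                    seed = 41)
  genes <- generate_gene_annotation(cfg)
  gt <- generate_genotypes(cfg, genes, generate_pathways(cfg, genes))
  ppi0 <- generate_ppi(cfg, genes, gt$truth)
  expect_equal(nrow(ppi0), 3L)
  expect_true(all(ppi0$gene_a < ppi0$gene_b))

  cfg_bg <- sim_config(n_genes = 100, n_cases = 50, n_controls = 50,
                       ppi_background_prob = 0.01, seed = 42)
  genes_bg <- generate_gene_annotation(cfg_bg)
  gt_bg <- generate_genotypes(cfg_bg, genes_bg,
                              generate_pathways(cfg_bg, genes_bg))
  ppi <- generate_ppi(cfg_bg, genes_bg, gt_bg$truth)
  expect_equal(anyDuplicated(paste(ppi$gene_a, ppi$gene_b)), 0L)
  expect_true(all(ppi$gene_a != ppi$gene_b))
  n_pairs <- choose(100, 2)
  mu <- 0.01 * n_pairs
  expect_lt(abs(nrow(ppi) - mu), 3 * sqrt(n_pairs * 0.01 * 0.99) + 1)
})

test_that("synthetic ontology depths match a BFS oracle and plant enrichment", {
  cfg <- sim_config(n_genes = 30, n_cases = 50, n_controls = 50, seed = 51)
  genes <- generate_gene_annotation(cfg)
  go <- generate_go(cfg, genes)
  onto <- go$ontology
  expect_gte(max(padnet:::.term_depth_table(onto)), 6)

  # BFS oracle over child adjacency, per namespace root
  depth_oracle <- setNames(rep(NA_integer_, nrow(onto$terms)),
                           onto$terms$term_id)
  for (root in onto$roots) {
    adj <- onto$children
    frontier <- root; depth_oracle[root] <- 1L; d <- 1L
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                     names(depth_oracle)[!is.na(depth_oracle)])
      depth_oracle[nxt] <- d + 1L
      frontier <- nxt; d <- d + 1L
    }
  }
  for (t in onto$terms$term_id)
    expect_identical(term_depth(onto, t), depth_oracle[[t]])

  tgt <- attr(go$annotations, "enriched_term")
  expect_true(tgt %in% onto$terms$term_id)
  expect_gte(term_depth(onto, tgt), 4)
  egenes <- attr(go$annotations, "enriched_genes")
  expect_true(all(paste(egenes, tgt) %in%
                  paste(go$annotations$gene_id, go$annotations$term_id)))
})
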