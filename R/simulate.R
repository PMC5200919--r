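#' Configure a synthetic case-control SNP study
#'
#' Defines the generating model for a complete synthetic input set:
#' genotypes with a binary phenotype from a logistic model with optional
#' planted pathway main effects and SNP-by-SNP interactions, gene
#' coordinates, pathway gene sets, PPI edges and a small gene ontology.
#' Identifiers are deterministic (`g001`, `g001_s1`, `pw01`, ...) so planted
#' effects can be declared up front, and a single `seed` fixes every output
#' bit-for-bit.
#'
#' The default sample size (2000 cases, 3000 controls) mirrors the
#' retrospective design of large public case-control GWAS resources; all
#' other defaults are chosen to give realistic but desk-scale data.
#'
#' @param n_cases,n_controls Number of cases / controls to emit (>= 1).
#' @param n_genes Number of genes.
#' @param snps_per_gene Integer range `c(min, max)` of SNPs hosted per gene.
#' @param maf_range Range of simulated minor allele frequencies, within
#'   (0, 0.5].
#' @param missing_rate Fraction of genotype calls set missing completely at
#'   random, in \[0, 0.5).
#' @param n_pathways Number of pathway gene sets.
#' @param pathway_size_range Integer range of genes per pathway; the
#'   maximum may not exceed `n_genes`.
#' @param pathway_overlap If `TRUE` (default) pathways are sampled
#'   independently and genes may belong to several pathways, as in curated
#'   pathway databases. If `FALSE` pathways partition disjoint gene blocks,
#'   which keeps non-risk pathways genuinely null in planted-effect
#'   recovery experiments (requires the total drawn sizes to fit in
#'   `n_genes`).
#' @param risk_pathways Planted pathway main effects: a list of
#'   `list(id = "pw01", beta = 0.4)` entries (or a named numeric vector);
#'   `beta` is the per-minor-allele log-odds added for every SNP mapped to
#'   the pathway's genes.
#' @param epistatic_pairs Planted interactions: a list of
#'   `list(snp_a = "g001_s1", snp_b = "g002_s1", gamma = 1.0)` entries.
#'   `gamma` is the log-odds coefficient of the dosage product. The two
#'   SNPs must sit in two distinct genes.
#' @param ppi_background_prob Probability that a random gene pair receives
#'   a background PPI edge.
#' @param ld_blocks If `TRUE`, SNPs within a gene share a latent haplotype
#'   so their pairwise dosage r-squared targets `ld_r2_target` (all SNPs of
#'   a gene then share one MAF); off by default so association experiments
#'   use independent markers.
#' @param ld_r2_target Target within-gene pairwise r-squared when
#'   `ld_blocks` is on.
#' @param chrom_length,max_chroms Chromosome length (bp) and maximum number
#'   of chromosomes available for packing gene intervals.
#' @param seed Integer root seed; per-stage streams are derived from it.
#' @return A validated `sim_config` object.
#' @seealso [generate_gene_annotation()], [generate_genotypes()]
#' @export
sim_config <- function(n_cases = 2000L, n_controls = 3000L,
                       n_genes = 50L, snps_per_gene = c(3L, 8L),
                       maf_range = c(0.05, 0.5), missing_rate = 0.02,
                       n_pathways = 10L, pathway_size_range = c(5L, 15L),
                       pathway_overlap = TRUE,
                       risk_pathways = list(), epistatic_pairs = list(),
                       ppi_background_prob = 0.01,
                       ld_blocks = FALSE, ld_r2_target = 0.9,
                       chrom_length = 5e6, max_chroms = 22L,
                       seed = 1L) {
  if (n_cases < 1 || n_controls < 1) stop("need at least one case and one control")
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (length(snps_per_gene) == 1) snps_per_gene <- rep(snps_per_gene, 2)
  if (snps_per_gene[1] > snps_per_gene[2] || snps_per_gene[1] < 1)
    stop("invalid snps_per_gene range")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 0.5)
    stop("missing_rate must lie in [0, 0.5)")
  if (length(pathway_size_range) == 1)
    pathway_size_range <- rep(pathway_size_range, 2)
  if (pathway_size_range[1] > pathway_size_range[2])
    stop("pathway size range is empty")
  if (pathway_size_range[2] > n_genes)
    stop("pathway_size_range max may not exceed n_genes")
  if (ppi_background_prob < 0 || ppi_background_prob > 1)
    stop("ppi_background_prob must lie in [0, 1]")
  if (ld_r2_target <= 0 || ld_r2_target > 1)
    stop("ld_r2_target must lie in (0, 1]")
  if (is.numeric(risk_pathways) && !is.null(names(risk_pathways)))
    risk_pathways <- lapply(seq_along(risk_pathways), function(i)
      list(id = names(risk_pathways)[i], beta = unname(risk_pathways[i])))
  for (rp in risk_pathways)
    if (!all(c("id", "beta") %in% names(rp)))
      stop("each risk pathway needs an 'id' and a 'beta'")
  if (anyDuplicated(vapply(risk_pathways, `[[`, "", "id")))
    stop("duplicated risk pathway ids")
  for (ep in epistatic_pairs) {
    if (!all(c("snp_a", "snp_b", "gamma") %in% names(ep)))
      stop("each epistatic pair needs 'snp_a', 'snp_b' and 'gamma'")
    if (ep$snp_a == ep$snp_b)
      stop("an epistatic pair must name two distinct SNPs")
    if (identical(.gene_of_snp(ep$snp_a), .gene_of_snp(ep$snp_b)))
      stop("planted epistatic SNPs must sit in two distinct genes")
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_genes = as.integer(n_genes), snps_per_gene = as.integer(snps_per_gene),
    maf_range = maf_range, missing_rate = missing_rate,
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    pathway_overlap = isTRUE(pathway_overlap),
    risk_pathways = risk_pathways, epistatic_pairs = epistatic_pairs,
    ppi_background_prob = ppi_background_prob,
    ld_blocks = isTRUE(ld_blocks), ld_r2_target = ld_r2_target,
    chrom_length = chrom_length, max_chroms = as.integer(max_chroms),
    seed = as.integer(seed)), class = "sim_config")
}

# gene id is the prefix of the deterministic SNP id "g001_s2" -> "g001"
.gene_of_snp <- function(snp_id) sub("_s[0-9]+$", "", snp_id)

.gene_ids <- function(n) sprintf("g%0*d", max(3L, nchar(n)), seq_len(n))
.pathway_ids <- function(n) sprintf("pw%0*d", max(2L, nchar(n)), seq_len(n))

# independent per-stage RNG streams derived from the root seed
.stage_seed <- function(seed, stage) {
  offs <- c(annotation = 101L, pathways = 211L, genotypes = 307L,
            ppi = 401L, go = 503L)
  (as.integer(seed) + offs[[stage]]) %% .Machine$integer.max
}

#' Generate non-overlapping gene coordinates
#'
#' Packs `n_genes` gene intervals left to right onto chromosomes of length
#' `chrom_length`, long enough to host each gene's SNPs and separated by
#' 11 kb gaps so that the default 5 kb flanks of neighbouring genes never
#' overlap. Coordinates are 0-based half-open (BED convention).
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `n_snps`.
#' @export
generate_gene_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config$seed, "annotation"))  # after forcing config
  n <- config$n_genes
  spg <- config$snps_per_gene
  n_snp <- if (spg[1] == spg[2]) rep(spg[1], n) else
    sample(seq(spg[1], spg[2]), n, replace = TRUE)
  gene_len <- n_snp * 500L + 500L
  gap <- 11000L
  chrom <- integer(n); start <- numeric(n)
  cur_chr <- 1L; cur_pos <- 0
  for (i in seq_len(n)) {
    if (gene_len[i] > config$chrom_length)
      stop("gene interval longer than the chromosome; increase chrom_length")
    if (cur_pos + gene_len[i] > config$chrom_length) {
      cur_chr <- cur_chr + 1L
      cur_pos <- 0
      if (cur_chr > config$max_chroms)
        stop("cannot pack ", n, " genes onto ", config$max_chroms,
             " chromosomes of length ", config$chrom_length)
    }
    chrom[i] <- cur_chr
    start[i] <- cur_pos
    cur_pos <- cur_pos + gene_len[i] + gap
  }
  data.frame(gene_id = .gene_ids(n), chrom = paste0("chr", chrom),
             start = as.integer(start), end = as.integer(start + gene_len),
             n_snps = as.integer(n_snp), stringsAsFactors = FALSE)
}

#' Generate pathway gene sets
#'
#' Draws `n_pathways` named gene sets with sizes uniform in
#' `pathway_size_range`; genes may belong to several pathways. Any pathway
#' id named in `config$risk_pathways` must exist in the output.
#'
#' @param config A [sim_config()].
#' @param genes Gene table from [generate_gene_annotation()].
#' @return Named list of sorted gene-id vectors, one per pathway.
#' @export
generate_pathways <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"))
  force(genes)   # evaluate promises before seeding the stage RNG
  set.seed(.stage_seed(config$seed, "pathways"))
  ids <- .pathway_ids(config$n_pathways)
  rng <- config$pathway_size_range
  sizes <- if (rng[1] == rng[2]) rep(rng[1], config$n_pathways) else
    sample(seq(rng[1], rng[2]), config$n_pathways, replace = TRUE)
  if (config$pathway_overlap) {
    pw <- lapply(sizes, function(s) sort(sample(genes$gene_id, s)))
  } else {
    if (sum(sizes) > nrow(genes))
      stop("disjoint pathways need sum(sizes) <= n_genes")
    perm <- sample(genes$gene_id)
    ends <- cumsum(sizes)
    pw <- lapply(seq_along(sizes), function(i)
      sort(perm[(ends[i] - sizes[i] + 1):ends[i]]))
  }
  names(pw) <- ids
  declared <- vapply(config$risk_pathways, `[[`, "", "id")
  missing_ids <- setdiff(declared, ids)
  if (length(missing_ids))
    stop("declared risk pathways not generated: ",
         paste(missing_ids, collapse = ", "))
  pw
}

# dosage batch under the configured marginal model; columns follow 'snps'
.gen_dosages <- function(m, snps, config) {
  p <- nrow(snps)
  if (!config$ld_blocks) {
    g <- matrix(rbinom(m * p, 2L, rep(snps$sim_maf, each = m)), m, p)
  } else {
    # per gene, haplotype alleles copy a shared anchor with probability
    # r2^(1/4): dosage correlation is copy_prob^2, so r2 = copy_prob^4
    cp <- config$ld_r2_target^(1 / 4)
    g <- matrix(0L, m, p)
    for (gn in unique(snps$gene_id)) {
      j <- which(snps$gene_id == gn)
      q <- snps$sim_maf[j[1]]
      a1 <- rbinom(m, 1L, q); a2 <- rbinom(m, 1L, q)
      for (k in j) {
        h1 <- ifelse(runif(m) < cp, a1, rbinom(m, 1L, q))
        h2 <- ifelse(runif(m) < cp, a2, rbinom(m, 1L, q))
        g[, k] <- h1 + h2
      }
    }
  }
  colnames(g) <- snps$snp_id
  g
}

#' Generate genotypes, phenotypes and the planted-truth record
#'
#' Draws per-SNP minor allele frequencies from `maf_range`, genotypes as
#' Binomial(2, MAF) dosages (optionally with within-gene LD), and the binary
#' phenotype from
#' \deqn{\mathrm{logit}\, P(y=1) = \beta_0 + \sum_j \beta_j g_j +
#'   \sum_{(a,b)} \gamma_{ab} g_a g_b,}
#' where the main effects come from the declared risk pathways and the
#' interaction terms from the planted epistatic pairs. The intercept
#' \eqn{\beta_0} is tuned by bisection (tolerance 1e-4 on the expected
#' prevalence) so that the population case fraction matches
#' `n_cases / (n_cases + n_controls)`; individuals are then sampled in
#' batches until the exact case and control quotas are filled, mimicking a
#' retrospective design. Missing calls are inserted completely at random at
#' `missing_rate`.
#'
#' @param config A [sim_config()].
#' @param genes Gene table from [generate_gene_annotation()].
#' @param pathways Pathway list from [generate_pathways()].
#' @return A list with elements `data` (a [genotype_dataset()]) and `truth`
#'   (risk/null pathway ids, planted pairs, per-SNP beta table, tuned
#'   intercept).
#' @export
generate_genotypes <- function(config, genes, pathways) {
  stopifnot(inherits(config, "sim_config"))
  force(genes); force(pathways)  # evaluate before seeding the stage RNG
  set.seed(.stage_seed(config$seed, "genotypes"))

  # SNP table: evenly spaced 1-based positions inside each gene body
  snps <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    k <- genes$n_snps[i]
    data.frame(
      snp_id = sprintf("%s_s%d", genes$gene_id[i], seq_len(k)),
      gene_id = genes$gene_id[i], chrom = genes$chrom[i],
      pos = genes$start[i] + 500L * seq_len(k) - 250L,
      stringsAsFactors = FALSE)
  }))
  p <- nrow(snps)
  if (config$ld_blocks) {
    maf_gene <- runif(nrow(genes), config$maf_range[1], config$maf_range[2])
    snps$sim_maf <- maf_gene[match(snps$gene_id, genes$gene_id)]
  } else {
    snps$sim_maf <- runif(p, config$maf_range[1], config$maf_range[2])
  }
  nuc <- c("A", "C", "G", "T")
  al <- t(vapply(seq_len(p), function(i) sample(nuc, 2), character(2)))
  snps$minor_allele <- al[, 1]
  snps$major_allele <- al[, 2]

  # planted effects
  beta <- setNames(rep(0, p), snps$snp_id)
  for (rp in config$risk_pathways) {
    gset <- pathways[[rp$id]]
    if (is.null(gset)) stop("risk pathway not found: ", rp$id)
    beta[snps$gene_id %in% gset] <- beta[snps$gene_id %in% gset] + rp$beta
  }
  pairs <- config$epistatic_pairs
  for (ep in pairs)
    if (!all(c(ep$snp_a, ep$snp_b) %in% snps$snp_id))
      stop("planted epistatic pair names an unknown SNP: ",
           ep$snp_a, " / ", ep$snp_b)
  ia <- match(vapply(pairs, `[[`, "", "snp_a"), snps$snp_id)
  ib <- match(vapply(pairs, `[[`, "", "snp_b"), snps$snp_id)
  gam <- vapply(pairs, `[[`, 0, "gamma")

  eta_of <- function(G) {
    e <- drop(G %*% beta)
    if (length(gam))
      for (k in seq_along(gam)) e <- e + gam[k] * G[, ia[k]] * G[, ib[k]]
    e
  }

  # tune the intercept on a fixed candidate pool by bisection
  target <- config$n_cases / (config$n_cases + config$n_controls)
  pool <- .gen_dosages(5000L, snps, config)
  eta_pool <- eta_of(pool)
  f <- function(b0) mean(plogis(b0 + eta_pool)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0)
    stop("cannot tune the intercept to the requested prevalence")
  beta0 <- NA_real_
  for (it in seq_len(200)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < 1e-4) { beta0 <- mid; break }
    if (fm > 0) hi <- mid else lo <- mid
  }
  if (is.na(beta0))
    stop("intercept tuning did not converge to the requested prevalence")

  # retrospective sampling: draw until the case/control quotas are exact
  need_case <- config$n_cases; need_ctrl <- config$n_controls
  batch <- max(2000L, 2L * (need_case + need_ctrl))
  cases <- list(); ctrls <- list()
  got_case <- 0L; got_ctrl <- 0L
  for (b in seq_len(60)) {
    G <- .gen_dosages(batch, snps, config)
    y <- rbinom(batch, 1L, plogis(beta0 + eta_of(G)))
    if (got_case < need_case) {
      take <- which(y == 1L)[seq_len(min(sum(y == 1L), need_case - got_case))]
      if (length(take)) { cases[[length(cases) + 1L]] <- G[take, , drop = FALSE]
                          got_case <- got_case + length(take) }
    }
    if (got_ctrl < need_ctrl) {
      take <- which(y == 0L)[seq_len(min(sum(y == 0L), need_ctrl - got_ctrl))]
      if (length(take)) { ctrls[[length(ctrls) + 1L]] <- G[take, , drop = FALSE]
                          got_ctrl <- got_ctrl + length(take) }
    }
    if (got_case >= need_case && got_ctrl >= need_ctrl) break
  }
  if (got_case < need_case || got_ctrl < need_ctrl)
    stop("could not reach the requested case/control counts; ",
         "planted effects make the prevalence unattainable")
  geno <- rbind(do.call(rbind, cases), do.call(rbind, ctrls))
  pheno <- c(rep(1L, need_case), rep(0L, need_ctrl))
  samples <- data.frame(
    sample_id = c(sprintf("case%05d", seq_len(need_case)),
                  sprintf("ctrl%05d", seq_len(need_ctrl))),
    phenotype = pheno, stringsAsFactors = FALSE)

  if (config$missing_rate > 0) {
    mask <- runif(length(geno)) < config$missing_rate
    geno[mask] <- NA_integer_
  }

  snps$maf <- .snp_maf(geno)
  snps$call_rate <- .snp_call_rate(geno)
  data <- genotype_dataset(geno, samples, snps)

  risk_ids <- vapply(config$risk_pathways, `[[`, "", "id")
  truth <- list(
    risk_pathway_ids = risk_ids,
    null_pathway_ids = setdiff(names(pathways), risk_ids),
    planted_pairs = if (length(pairs)) data.frame(
      snp_a = vapply(pairs, `[[`, "", "snp_a"),
      snp_b = vapply(pairs, `[[`, "", "snp_b"),
      gene_a = .gene_of_snp(vapply(pairs, `[[`, "", "snp_a")),
      gene_b = .gene_of_snp(vapply(pairs, `[[`, "", "snp_b")),
      gamma = gam, stringsAsFactors = FALSE)
    else data.frame(snp_a = character(), snp_b = character(),
                    gene_a = character(), gene_b = character(),
                    gamma = numeric()),
    beta_table = data.frame(snp_id = snps$snp_id, beta = unname(beta),
                            stringsAsFactors = FALSE),
    intercept = beta0)
  list(data = data, truth = truth)
}

#' Generate a PPI edge table
#'
#' Emits an undirected simple edge list over the gene universe: every
#' planted epistatic gene pair is always included (so end-to-end recovery
#' of planted interactions is well-posed), and each remaining gene pair is
#' added independently with probability `ppi_background_prob`.
#'
#' @param config A [sim_config()].
#' @param genes Gene table from [generate_gene_annotation()].
#' @param truth Truth record from [generate_genotypes()].
#' @return Data frame with columns `gene_a`, `gene_b` in canonical
#'   (lexicographic) order, no self-loops or duplicates.
#' @export
generate_ppi <- function(config, genes, truth) {
  stopifnot(inherits(config, "sim_config"))
  force(genes); force(truth)     # evaluate before seeding the stage RNG
  set.seed(.stage_seed(config$seed, "ppi"))
  ids <- genes$gene_id
  planted <- unique(data.frame(
    gene_a = pmin(truth$planted_pairs$gene_a, truth$planted_pairs$gene_b),
    gene_b = pmax(truth$planted_pairs$gene_a, truth$planted_pairs$gene_b),
    stringsAsFactors = FALSE))
  if (any(planted$gene_a == planted$gene_b))
    stop("planted PPI pairs may not be self-pairs")
  bg <- data.frame(gene_a = character(), gene_b = character())
  if (length(ids) >= 2 && config$ppi_background_prob > 0) {
    cmb <- t(combn(sort(ids), 2))
    keep <- runif(nrow(cmb)) < config$ppi_background_prob
    bg <- data.frame(gene_a = cmb[keep, 1], gene_b = cmb[keep, 2],
                     stringsAsFactors = FALSE)
  }
  out <- unique(rbind(planted, bg))
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a synthetic gene ontology and annotations
#'
#' Builds a rooted DAG of terms for each namespace (a 7-level BP graph in
#' which some terms carry a second, shallower parent, plus small CC and MF
#' chains), annotates genes to random terms, and plants one guaranteed
#' enrichment signal: all `enriched_genes` are annotated to a single BP
#' term of depth >= 4 (recorded in the `"enriched_term"` attribute of the
#' annotation table).
#'
#' @param config A [sim_config()].
#' @param genes Gene table from [generate_gene_annotation()].
#' @param enriched_genes Genes carrying the planted signal; defaults to the
#'   first `min(10, n_genes)` genes.
#' @return A list with `annotations` (data frame `gene_id`, `term_id`) and
#'   `ontology` (a [go_ontology()]).
#' @export
generate_go <- function(config, genes, enriched_genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  force(genes); force(enriched_genes)
  set.seed(.stage_seed(config$seed, "go"))
  if (is.null(enriched_genes))
    enriched_genes <- head(genes$gene_id, 10L)
  stopifnot(all(enriched_genes %in% genes$gene_id))

  counter <- 0L
  new_terms <- function(k, ns) {
    ids <- sprintf("GO:%07d", counter + seq_len(k))
    counter <<- counter + k
    data.frame(term_id = ids, name = paste0("synthetic term ", ids),
               namespace = ns, stringsAsFactors = FALSE)
  }
  terms <- list(); edges <- list()
  # BP: 7 levels; each term has one parent in the level above and, with
  # probability 0.25, an extra parent two levels up (a DAG, not a tree)
  sizes <- c(1L, 3L, 5L, 8L, 8L, 6L, 4L)
  levels <- lapply(seq_along(sizes), function(d) new_terms(sizes[d], "BP"))
  for (d in 2:length(sizes)) {
    ch <- levels[[d]]$term_id
    par1 <- sample(levels[[d - 1]]$term_id, length(ch), replace = TRUE)
    edges[[length(edges) + 1L]] <- data.frame(child = ch, parent = par1)
    if (d > 3) {
      extra <- runif(length(ch)) < 0.25
      if (any(extra)) {
        par2 <- sample(levels[[d - 2]]$term_id, sum(extra), replace = TRUE)
        edges[[length(edges) + 1L]] <- data.frame(child = ch[extra],
                                                  parent = par2)
      }
    }
  }
  terms <- do.call(rbind, levels)
  # CC and MF: 4-level chains with a little branching
  for (ns in c("CC", "MF")) {
    lv <- lapply(c(1L, 2L, 3L, 3L), function(k) new_terms(k, ns))
    for (d in 2:4) {
      ch <- lv[[d]]$term_id
      par1 <- sample(lv[[d - 1]]$term_id, length(ch), replace = TRUE)
      edges[[length(edges) + 1L]] <- data.frame(child = ch, parent = par1)
    }
    terms <- rbind(terms, do.call(rbind, lv))
  }
  edges <- do.call(rbind, edges)
  onto <- go_ontology(terms, edges)
  depth <- .term_depth_table(onto)

  # random direct annotations to mid/deep terms of any namespace
  pool <- terms$term_id[depth >= 3]
  ann <- do.call(rbind, lapply(genes$gene_id, function(g) {
    k <- sample(1:3, 1)
    data.frame(gene_id = g, term_id = sample(pool, k),
               stringsAsFactors = FALSE)
  }))
  # planted signal: one deep BP term annotated with the designated set
  bp_deep <- terms$term_id[terms$namespace == "BP" & depth >= 4]
  target <- sample(bp_deep, 1)
  ann <- unique(rbind(ann, data.frame(gene_id = enriched_genes,
                                      term_id = target,
                                      stringsAsFactors = FALSE)))
  ann <- ann[order(ann$gene_id, ann$term_id), ]
  rownames(ann) <- NULL
  attr(ann, "enriched_term") <- target
  attr(ann, "enriched_genes") <- enriched_genes
  list(annotations = ann, ontology = onto)
}

#' Generate every pipeline input in one call
#'
#' Convenience wrapper running the annotation, pathway, genotype, PPI and
#' GO generators in order with the config's derived seeds.
#'
#' @param config A [sim_config()].
#' @return A list with `genes`, `pathways`, `data`, `truth`, `ppi`,
#'   `annotations`, `ontology`.
#' @export
simulate_study <- function(config) {
  genes <- generate_gene_annotation(config)
  pathways <- generate_pathways(config, genes)
  gt <- generate_genotypes(config, genes, pathways)
  ppi <- generate_ppi(config, genes, gt$truth)
  risk_genes <- unique(unlist(pathways[gt$truth$risk_pathway_ids],
                              use.names = FALSE))
  go <- generate_go(config, genes,
                    enriched_genes = if (length(risk_genes))
                      head(risk_genes, 10L) else NULL)
  list(genes = genes, pathways = pathways, data = gt$data,
       truth = gt$truth, ppi = ppi,
       annotations = go$annotations, ontology = go$ontology)
}
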