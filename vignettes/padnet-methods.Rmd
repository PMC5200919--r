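---
title: "Pathway association and genetic network discovery with padnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway association and genetic network discovery with padnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padnet)
```

## The analysis problem

Single-locus genome-wide association scans capture only markers with strong
marginal effects. For complex traits such as coronary artery disease, much of
the genetic signal is expected to act jointly — several modest variants in the
same biological pathway, or pairs of loci whose effect is non-additive. padnet
implements a workflow that targets exactly this joint structure in
case-control SNP data:

1. **Genotype quality control**: missingness, minor allele frequency (MAF)
   and Hardy–Weinberg equilibrium (HWE) screens, modal-genotype imputation,
   sliding-window tag-SNP pruning, and mapping of SNPs to genes through
   flanking windows.
2. **Pathway-level association**: the logistic kernel machine regression
   score test applied to each pathway's SNP set, with Bonferroni control
   over pathways.
3. **Epistasis scanning**: an exhaustive logistic interaction-model scan over
   all SNP pairs of the significant pathways, retained at a nominal
   threshold.
4. **Network construction**: gene pairs supported by *both* a retained
   statistical interaction and a recorded protein–protein interaction (PPI)
   become edges of a genetic network, which is then characterised
   topologically (scale-free test, Poisson hub test) and decomposed into
   modules by modularity maximisation.
5. **Functional annotation**: hypergeometric GO over-representation of each
   module, restricted to informative ontology depths.

Because the archetypal input (a consortium case-control genotype panel) is
access-controlled, the package ships a fully seeded synthetic-data generator
with planted effects, so every stage can be tested for calibration and
recovery without any external data.

## The kernel machine score test

For a pathway whose genes carry $p$ SNPs with dosage codes
$z_{i1},\dots,z_{ip} \in \{0,1,2\}$ (minor-allele counts) for subject $i$,
the semi-parametric model is

$$\operatorname{logit} P(y_i = 1) = \alpha_0 + h(z_{i1},\dots,z_{ip}),$$

where $h$ lives in the function space induced by a positive semi-definite
kernel $K(\cdot,\cdot)$. The default kernel is the weighted linear kernel

$$K(Z_i, Z_{i'}) = \sum_{j=1}^{p} w_j\, z_{ij} z_{i'j},$$

with Gaussian and identity-by-state kernels available. The null hypothesis
$h \equiv 0$ is tested with the variance-component score statistic

$$Q = \tfrac{1}{2} (y - \hat\mu_0)^\top K (y - \hat\mu_0),$$

where $\hat\mu_0$ are fitted probabilities of the null (intercept-only by
default) logistic model. Under $H_0$, $Q$ follows a mixture
$\sum_k \lambda_k \chi^2_{1,k}$ whose weights are the eigenvalues of
$\tfrac12 P_0^{1/2} K P_0^{1/2}$ with
$P_0 = D - DX(X^\top D X)^{-1} X^\top D$ and
$D = \operatorname{diag}(\hat\mu_0 (1-\hat\mu_0))$. For the linear kernel
the non-zero eigenvalues are computed from the $p \times p$ matrix
$\tfrac12 G^\top P_0 G$ (with $G = Z\,\mathrm{diag}(\sqrt w)$), which keeps a
genome-scale scan tractable; the dense route is retained for arbitrary
kernels and as an oracle in the tests.

**Tail probability.** The mixture tail is evaluated by numerical inversion
of the quadratic form's characteristic function (the Imhof/Davies family):

$$P(Q > q) = \frac12 + \frac{1}{\pi}\int_0^\infty
  \frac{\sin\theta(u)}{u\,\rho(u)}\,du,$$

with $\theta(u) = \tfrac12\sum_k \arctan(\lambda_k u) - \tfrac12 qu$ and
$\rho(u) = \prod_k (1+\lambda_k^2u^2)^{1/4}$, using adaptive quadrature
with a tolerance cascade ($10^{-8}$, then $10^{-6}$). If the integration
fails or underflows, a moment-matched non-central chi-square approximation
(Liu type) takes over and the fallback is recorded in the result's
`method_used` attribute. Single-eigenvalue cases reduce exactly to the
1-df chi-square survival function, which the tests exploit as a closed-form
oracle; a Monte-Carlo oracle covers multi-eigenvalue cases.

**Weights.** The default weight of SNP $j$ is the squared Beta(1, 25)
density at its MAF — the rare-variant convention of the SKAT family. For
common-variant designs (genotyping arrays, simulated MAFs in 0.05–0.5) this
scheme deliberately discards most of the common signal, so recovery
experiments in this package use the flat scheme (`weight_scheme = "flat"`);
both are exposed through `kernel_spec()`. This is a genuine analysis choice,
not a tuning knob: beta weights answer a rare-variant question, flat weights
the array-era question this workflow emulates.

```{r kernel-example}
spec <- kernel_spec(weight_scheme = "flat")
pvalue_mixture_chisq(5, c(2, 1))
```

## Known small-sample behaviour

The mixture null treats the phenotype entries as independent Bernoulli draws;
a permutation test conditions on the observed case count, which scales the
residual covariance by $n/(n-1)$ and changes fourth moments. At $n = 60$ the
two nulls agree closely in the tail (p below roughly 0.15, the regime where
significance decisions live) but can differ by a few hundredths in the
mid-range of the distribution. The permutation-equivalence test therefore
uses a moderate-signal fixture. At $n \ge 500$ the type-I error of the
analytic p-value is indistinguishable from nominal (see the calibration
test: 1,000 null replicates at $n = 500$).

## Epistasis scan

Every unordered pair of SNPs in the union of the significant pathways is
tested with the full logistic interaction model

$$\operatorname{logit} P(y=1) = b_0 + b_1 g_1 + b_2 g_2 + b_3 g_1 g_2,$$

fitted by Newton/IRLS (step tolerance $10^{-8}$, at most 50 iterations) with
a two-sided Wald test of $b_3 = 0$. Pairs with a constant dosage or product
column are reported not testable; coefficients beyond $\pm 15$ flag
quasi-separation and exclude the pair downstream. No multiple-testing
correction is applied at this stage: the nominal $P < 0.05$ screen is
deliberately permissive, and the false positives it admits are pruned by the
requirement that a network edge also be a recorded PPI. The scan's retained
fraction under the global null concentrates at the nominal level
(binomial-band test over 19,900 pairs).

## Network, hubs, scale-freeness, modules

The gene network's edge set is the intersection of epistatic gene-pair
candidates and the PPI table; candidate genes without a supported edge stay
as isolated nodes so the component census is honest. Topology (degree,
betweenness, local clustering, diameter) and community structure come from
igraph. Module decomposition uses fast-greedy modularity maximisation
(Newman-style agglomeration; leading-eigenvector available), with the
dendrogram cut exactly at its recorded modularity maximum — `membership()`
alone can sit one merge short of the optimum on highly symmetric graphs.

**Hub calling.** Under a homogeneous null the degree of a node is
approximately Poisson with mean $\lambda = 2E/V$ of the graph under test;
each node's upper tail $P(X \ge \text{degree})$ is Bonferroni-corrected over
the $V$ nodes and hubs are called at adjusted $P < 0.05$. Both conventions
($\lambda$ from the tested subgraph, correction over its node count) are
explicit because published analyses rarely state them.

**Scale-free test.** The degree distribution is fitted with the exact
discrete maximum-likelihood estimator of $p(k) \propto k^{-\alpha}$,
$k \ge x_{\min}$ (numerical minimisation of
$\alpha \sum_i \ln k_i + n \ln \zeta(\alpha, x_{\min})$, Hurwitz zeta by
Euler–Maclaurin summation). The frequently quoted closed-form shortcut
$\hat\alpha = 1 + n / \sum_i \ln\!\big(k_i/(x_{\min}-\tfrac12)\big)$ is
*not* used as the estimate: at $x_{\min} = 1$ it is biased toward
$\hat\alpha \approx 2.2$ for a true $\alpha = 3$ and would make exponent
recovery impossible; it only centres the search bracket. Goodness of fit is
the KS sup-distance between empirical and fitted CDFs with a seeded
parametric bootstrap p-value (default 1,000 replicates): a high p-value
means the power law is not rejected. Self-consistency (recovery of
$\alpha = 3$ within $\pm 0.3$ with $p > 0.1$) and power against Poisson
degree data are both exercised in the test suite.

## GO enrichment

Annotations are propagated up `is_a` edges (true-path rule), and each
module of at least 10 genes is tested term-by-term with the one-sided
hypergeometric tail $P(X \ge k)$ against the background universe
(all annotated genes by default). Bonferroni correction is per module over
the terms with at least one module gene. Reports keep terms of depth
$\ge 4$, where depth is 1 plus the shortest `is_a` path to the namespace
root (roots sit at depth 1; a term with parents at depths 2 and 5 has
depth 3). The published procedure this emulates used an analysis tool whose
default score subtracts one overlapping gene; that EASE variant is available
via `ease = TRUE` but the plain tail is the default. The hypergeometric
tail is verified against one-sided Fisher exact tests to $10^{-12}$ on 200
random configurations.

Two conventions deserve note: the 10-gene module threshold is *inclusive*
(published tables include 10-gene modules despite the prose saying "more
than 10"), and both raw and Bonferroni-adjusted p-values are always emitted
because published module tables do not state which they print.

## The synthetic-data generator

`sim_config()` fixes the whole study: sample sizes (default 2,000 cases /
3,000 controls, emulating the retrospective design of the archetypal
consortium panel), gene and pathway structure, per-SNP MAFs drawn from
(0.05, 0.5], missingness (2% MCAR by default), and the planted truth. The
phenotype follows

$$\operatorname{logit} P(y_i=1) = \beta_0 + \textstyle\sum_j \beta_j g_{ij}
  + \sum_{(a,b)} \gamma_{ab}\, g_{ia} g_{ib},$$

with $\beta_j$ set per declared risk pathway and $\gamma_{ab}$ per planted
SNP pair. The intercept is tuned by bisection (tolerance $10^{-4}$ on the
expected prevalence over a fixed 5,000-individual genotype pool) and
individuals are then sampled in batches until the case and control quotas
are met exactly. Identifiers are deterministic (`g001`, `g001_s1`, `pw01`),
so planted effects can name their loci up front, and a single root seed
derives one RNG stream per stage — all generator arguments are forced before
the stream is seeded, so nested calls cannot desynchronise stages.

Design choices worth stating:

* **Pathway overlap.** By default pathways are sampled with replacement
  across genes, as in curated databases. `pathway_overlap = FALSE` makes
  them partition disjoint gene blocks — used in recovery experiments, where
  a "null" pathway sharing a risk gene would otherwise not be null.
* **LD.** Off by default (independent markers), because the association
  tests assume pruned data. `ld_blocks = TRUE` gives within-gene blocks a
  common MAF and a latent-haplotype copying structure whose copy probability
  is $r^2_{\text{target}}{}^{1/4}$, so pairwise dosage $r^2$ targets the
  requested value; this is what the pruning tests exercise.
* **PPI.** Planted epistatic gene pairs are always present in the PPI table
  (so end-to-end recovery is well-posed); background edges appear
  independently with a configurable probability.
* **Ontology.** A 7-level BP DAG (some terms carry a second, shallower
  parent) plus small CC/MF graphs; one deep BP term is annotated with a
  designated gene set, so enrichment has a planted positive control.

What the generator does **not** emulate: realistic human LD maps and
recombination structure, population stratification, genotyping batch
effects, and informative missingness. Passing tests therefore demonstrate
calibration and recovery under a clean generative model, not robustness to
those real-data complications.

## Problem sizes used in the validation suite

The shipped tests run, among others: 1,000 null replicates of the kernel
test at $n = 500$ with 20 SNPs (type-I error within the binomial band
around 0.05); 50 planted-pathway replicates at $n = 2{,}000$ with 20
disjoint pathways (rank-1 recovery $\ge$ 90%); an exhaustive 19,900-pair
null epistasis scan; 20+20 power-law replicates at $n = 500$ with 1,000
bootstrap draws each; and a double end-to-end pipeline run compared file by
file for bit-identical outputs. These sizes keep the whole suite within a
few minutes on one CPU while leaving the binomial test bands meaningful.

## A complete run

```{r pipeline, eval = FALSE}
sim <- sim_config(
  n_cases = 600, n_controls = 900, n_genes = 40, snps_per_gene = c(3, 5),
  n_pathways = 8, pathway_size_range = c(5, 5), pathway_overlap = FALSE,
  risk_pathways = list(list(id = "pw01", beta = 0.4)),
  epistatic_pairs = list(
    list(snp_a = "g008_s1", snp_b = "g014_s1", gamma = 1.2)),
  seed = 11)
rc <- run_config(sim = sim, out_dir = "padnet_run",
                 kernel = kernel_spec(weight_scheme = "flat"))
report <- run_pipeline(rc)
report
```

Each stage writes its tables (dosage TSV, QC report JSON, pathway results,
retained SNP pairs, gene pairs, GraphML network, hub and module tables,
enrichment rows) under `out_dir` before the next stage starts; the JSON run
report embeds the verbatim configuration and per-stage counts so a run can
be narrated and reproduced. If no pathway survives the Bonferroni screen
the pipeline ends after the association stage with an explicit
empty-downstream report rather than an error.

## Limitations

* The score test's analytic null is slightly conservative in very small
  samples; no small-sample moment correction is implemented.
* The epistasis scan is restricted to the SNPs of the significant pathways
  (quadratic cost); genome-wide all-pairs scanning is out of scope.
* Bonferroni is the only family-wise correction offered at the pathway and
  module stages, matching the emulated procedure.
* The OBO reader covers the minimal subset the pipeline writes (`[Term]`,
  `id`, `name`, `namespace`, `is_a`); `part_of` relations are ignored by
  design for depth and propagation.
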