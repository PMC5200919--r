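#' Configure a full pipeline run
#'
#' Collects every stage's parameters with defaults matching standard GWAS
#' practice for this workflow: SNP/sample missingness 0.05, MAF 0.01,
#' control-group HWE 1e-4, pruning window 50 SNPs / step 5 / r-squared 0.8,
#' 5 kb gene flanks, Bonferroni pathway significance at 0.05, nominal
#' epistasis retention at 0.05, Poisson hub calling at 0.05 and GO reports
#' at depth >= 4 for modules of at least 10 genes. The effective config is
#' serialised verbatim into the run report for provenance.
#'
#' @param sim A [sim_config()] describing the synthetic inputs.
#' @param out_dir Output directory (created if needed); stage outputs are
#'   written under it.
#' @param snp_miss_max,sample_miss_max,maf_min,hwe_alpha QC thresholds,
#'   see [filter_dataset()].
#' @param prune_window,prune_step,prune_r2 Tag-SNP pruning parameters.
#' @param flank SNP-to-gene mapping flank (bp).
#' @param kernel A [kernel_spec()].
#' @param pathway_alpha Family-wise level of the Bonferroni pathway screen.
#' @param epistasis_alpha Nominal retention threshold of the pair scan.
#' @param network_algorithm Modularity algorithm, see
#'   [decompose_modules()].
#' @param powerlaw_xmin,powerlaw_nboot Scale-free test parameters.
#' @param go_min_depth,go_min_module_size GO enrichment filters.
#' @param stages Stage names to run, in pipeline order; later stages are
#'   skipped automatically when a prerequisite did not run.
#' @param seed Root seed (propagated to `sim` and all stochastic stages).
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(), out_dir = tempfile("padnet_run_"),
                       snp_miss_max = 0.05, sample_miss_max = 0.05,
                       maf_min = 0.01, hwe_alpha = 1e-4,
                       prune_window = 50L, prune_step = 5L, prune_r2 = 0.8,
                       flank = 5000L, kernel = kernel_spec(),
                       pathway_alpha = 0.05, epistasis_alpha = 0.05,
                       network_algorithm = "fast_greedy",
                       powerlaw_xmin = 1L, powerlaw_nboot = 1000L,
                       go_min_depth = 4L, go_min_module_size = 10L,
                       stages = c("simulate", "qc", "assoc", "epistasis",
                                  "network", "enrich"),
                       seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(
    sim = sim, out_dir = out_dir, snp_miss_max = snp_miss_max,
    sample_miss_max = sample_miss_max, maf_min = maf_min,
    hwe_alpha = hwe_alpha, prune_window = as.integer(prune_window),
    prune_step = as.integer(prune_step), prune_r2 = prune_r2,
    flank = as.integer(flank), kernel = kernel,
    pathway_alpha = pathway_alpha, epistasis_alpha = epistasis_alpha,
    network_algorithm = network_algorithm,
    powerlaw_xmin = as.integer(powerlaw_xmin),
    powerlaw_nboot = as.integer(powerlaw_nboot),
    go_min_depth = as.integer(go_min_depth),
    go_min_module_size = as.integer(go_min_module_size),
    stages = stages, seed = sim$seed), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; the `sim` and
#' `kernel` blocks are passed to [sim_config()] / [kernel_spec()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  kern_args <- y$kernel %||% list()
  y$sim <- do.call(sim_config, sim_args)
  y$kernel <- do.call(kernel_spec, kern_args)
  do.call(run_config, y)
}

.stage_time <- function(expr) {
  t0 <- Sys.time()
  value <- expr
  list(value = value, seconds = as.numeric(Sys.time() - t0, units = "secs"))
}

#' Run the full synthetic-to-enrichment pipeline
#'
#' Executes simulate, qc (filter, impute, prune, map), assoc (pathway
#' SNP-set tests), epistasis (pair scan over significant pathways and
#' gene-pair translation), network (PPI-supported graph, largest component,
#' topology, scale-free fit when the component is large enough, hub test,
#' modularity decomposition) and enrich (per-module GO), in this fixed
#' order. Each stage writes its result tables under `config$out_dir`
#' before the next starts, and a JSON run report with per-stage counts,
#' timings and the verbatim config is written at the end. When no pathway
#' passes the Bonferroni screen the pipeline ends after the association
#' stage with an explicit empty-downstream report rather than an error.
#' Rerunning with an identical config reproduces identical result tables.
#'
#' @param config A [run_config()].
#' @return A `run_report` list (also written to
#'   `out_dir/run_report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$sim$seed, stages_run = character(),
                 counts = list(), timing = list(),
                 empty_downstream = FALSE)
  want <- function(s) s %in% config$stages
  state <- list()

  if (want("simulate")) {
    st <- .stage_time({
      sim <- simulate_study(config$sim)
      d <- file.path(config$out_dir, "sim")
      dir.create(d, showWarnings = FALSE)
      write_gene_bed(sim$genes, file.path(d, "genes.bed"))
      write_gmt(sim$pathways, file.path(d, "pathways.gmt"))
      write_dosage_tsv(sim$data, file.path(d, "dosages.tsv"),
                       file.path(d, "snps.tsv"))
      write_edge_tsv(sim$ppi, file.path(d, "ppi.tsv"))
      write_edge_tsv(sim$annotations, file.path(d, "go_annotations.tsv"))
      write_obo(sim$ontology, file.path(d, "ontology.obo"))
      write_truth_json(sim$truth, file.path(d, "truth.json"))
      sim
    })
    state$sim <- st$value
    report$stages_run <- c(report$stages_run, "simulate")
    report$timing$simulate <- st$seconds
    report$counts$simulate <- list(
      n_samples = nrow(state$sim$data$geno),
      n_snps = ncol(state$sim$data$geno),
      n_genes = nrow(state$sim$genes),
      n_pathways = length(state$sim$pathways),
      n_ppi_edges = nrow(state$sim$ppi))
  }

  if (want("qc") && !is.null(state$sim)) {
    st <- .stage_time({
      f <- filter_dataset(state$sim$data, config$snp_miss_max,
                          config$sample_miss_max, config$maf_min,
                          config$hwe_alpha)
      imp <- impute_most_frequent(f$data)
      pr <- prune_tag_snps(imp, config$prune_window, config$prune_step,
                           config$prune_r2)
      map <- map_snps_to_genes(pr$data$snps, state$sim$genes, config$flank)
      d <- file.path(config$out_dir, "qc")
      dir.create(d, showWarnings = FALSE)
      write_dosage_tsv(pr$data, file.path(d, "dosages_qc.tsv"),
                       file.path(d, "snps_qc.tsv"))
      jsonlite::write_json(
        list(report = f$report[c("thresholds", "filter_order",
                                 "n_snps_in", "n_snps_out",
                                 "n_samples_in", "n_samples_out")],
             n_pruned = length(pr$removed)),
        file.path(d, "qc_report.json"), auto_unbox = TRUE, pretty = TRUE)
      write_edge_tsv(map, file.path(d, "snp_gene_map.tsv"))
      list(data = pr$data, map = map, qc = f$report, pruned = pr$removed)
    })
    state$qc <- st$value
    report$stages_run <- c(report$stages_run, "qc")
    report$timing$qc <- st$seconds
    report$counts$qc <- list(
      n_snps_after_filters = state$qc$qc$n_snps_out,
      n_samples_after_filters = state$qc$qc$n_samples_out,
      n_snps_pruned = length(state$qc$pruned),
      n_tag_snps = ncol(state$qc$data$geno),
      n_mapped_snps = length(unique(state$qc$map$snp_id)))
  }

  if (want("assoc") && !is.null(state$qc)) {
    st <- .stage_time({
      sets <- make_snp_sets(state$sim$pathways, state$qc$map)
      res <- test_pathways(state$qc$data, sets, config$kernel,
                           alpha = config$pathway_alpha)
      d <- file.path(config$out_dir, "assoc")
      dir.create(d, showWarnings = FALSE)
      write_edge_tsv(res, file.path(d, "pathway_results.tsv"))
      list(sets = sets, results = res)
    })
    state$assoc <- st$value
    report$stages_run <- c(report$stages_run, "assoc")
    report$timing$assoc <- st$seconds
    sig_ids <- state$assoc$results$pathway_id[state$assoc$results$significant]
    report$counts$assoc <- list(
      n_pathways_tested = length(state$assoc$sets),
      n_significant = length(sig_ids),
      significant_pathways = sig_ids)
    if (length(sig_ids) == 0 &&
        any(c("epistasis", "network", "enrich") %in% config$stages)) {
      report$empty_downstream <- TRUE
      report$note <- "no significant pathways; downstream stages not run"
      return(.finish_report(report, config))
    }
    state$sig_sets <- Filter(function(s) s$pathway_id %in% sig_ids,
                             state$assoc$sets)
  }

  if (want("epistasis") && !is.null(state$sig_sets)) {
    st <- .stage_time({
      pairs <- scan_significant_pathways(state$qc$data, state$sig_sets,
                                         config$epistasis_alpha)
      cand <- pairs_to_genes(pairs, state$qc$map)
      d <- file.path(config$out_dir, "epistasis")
      dir.create(d, showWarnings = FALSE)
      write_edge_tsv(pairs, file.path(d, "snp_pairs.tsv"))
      write_edge_tsv(cand, file.path(d, "gene_pairs.tsv"))
      list(pairs = pairs, candidates = cand)
    })
    state$epi <- st$value
    report$stages_run <- c(report$stages_run, "epistasis")
    report$timing$epistasis <- st$seconds
    report$counts$epistasis <- list(
      n_pairs_tested = attr(state$epi$pairs, "n_pairs_tested"),
      n_pairs_retained = attr(state$epi$pairs, "n_retained"),
      n_gene_pair_candidates = nrow(state$epi$candidates))
  }

  if (want("network") && !is.null(state$epi)) {
    st <- .stage_time({
      net <- build_network(state$epi$candidates, state$sim$ppi)
      d <- file.path(config$out_dir, "network")
      dir.create(d, showWarnings = FALSE)
      igraph::write_graph(net, file.path(d, "network.graphml"),
                          format = "graphml")
      out <- list(net = net)
      if (igraph::vcount(net) > 0 && igraph::ecount(net) > 0) {
        lc <- largest_component(net)
        out$lc <- lc
        out$topo <- topology_stats(lc)
        write_edge_tsv(out$topo$nodes, file.path(d, "node_topology.tsv"))
        if (igraph::vcount(lc) >= 2) {
          out$hubs <- hub_test(lc)
          write_edge_tsv(out$hubs, file.path(d, "hub_results.tsv"))
        }
        deg <- igraph::degree(lc)
        if (sum(deg >= config$powerlaw_xmin) >= 10 &&
            length(unique(deg[deg >= config$powerlaw_xmin])) > 1) {
          out$plaw <- fit_power_law(deg, config$powerlaw_xmin,
                                    config$powerlaw_nboot,
                                    seed = config$sim$seed)
        }
        out$modules <- decompose_modules(lc, config$network_algorithm)
        write_edge_tsv(
          data.frame(gene = names(out$modules$assignment),
                     module = as.integer(out$modules$assignment)),
          file.path(d, "module_assignment.tsv"))
        write_edge_tsv(out$modules$modules,
                       file.path(d, "module_topology.tsv"))
      }
      out
    })
    state$net <- st$value
    report$stages_run <- c(report$stages_run, "network")
    report$timing$network <- st$seconds
    census <- if (!is.null(state$net$lc))
      as.integer(attr(state$net$lc, "component_census")) else integer()
    report$counts$network <- list(
      n_nodes = igraph::vcount(state$net$net),
      n_edges = igraph::ecount(state$net$net),
      n_components = if (igraph::vcount(state$net$net))
        igraph::components(state$net$net)$no else 0L,
      largest_component_nodes = if (!is.null(state$net$lc))
        igraph::vcount(state$net$lc) else 0L,
      largest_component_edges = if (!is.null(state$net$lc))
        igraph::ecount(state$net$lc) else 0L,
      n_modules = if (!is.null(state$net$modules))
        nrow(state$net$modules$modules) else 0L,
      modularity_q = if (!is.null(state$net$modules))
        state$net$modules$modularity_q else NA,
      n_hubs = if (!is.null(state$net$hubs))
        sum(state$net$hubs$is_hub) else 0L,
      powerlaw_alpha = if (!is.null(state$net$plaw))
        state$net$plaw$alpha else NA,
      powerlaw_p = if (!is.null(state$net$plaw))
        state$net$plaw$p_value else NA)
  }

  if (want("enrich") && !is.null(state$net$modules)) {
    st <- .stage_time({
      enr <- enrich_modules(state$net$modules, state$sim$annotations,
                            state$sim$ontology,
                            min_depth = config$go_min_depth,
                            min_module_size = config$go_min_module_size)
      d <- file.path(config$out_dir, "enrich")
      dir.create(d, showWarnings = FALSE)
      write_edge_tsv(enr, file.path(d, "module_enrichment.tsv"))
      enr
    })
    state$enr <- st$value
    report$stages_run <- c(report$stages_run, "enrich")
    report$timing$enrich <- st$seconds
    report$counts$enrich <- list(
      n_enriched_terms = nrow(state$enr),
      n_modules_skipped = length(attr(state$enr, "skipped_modules")))
  }

  rep <- .finish_report(report, config)
  attr(rep, "state") <- state
  rep
}

.finish_report <- function(report, config) {
  cfg <- config
  cfg$sim <- unclass(cfg$sim)
  cfg$kernel <- unclass(cfg$kernel)
  report$config <- unclass(cfg)
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report),
                       file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed ", x$seed, ")\n", sep = "")
  for (s in x$stages_run) {
    cat(sprintf("  %-9s %5.1fs", s, x$timing[[s]]))
    cnt <- x$counts[[s]]
    if (!is.null(cnt)) {
      scalars <- cnt[vapply(cnt, function(v)
        length(v) == 1 && !is.list(v), TRUE)]
      cat("  ", paste(names(scalars), unlist(scalars), sep = "=",
                      collapse = ", "))
    }
    cat("\n")
  }
  if (isTRUE(x$empty_downstream)) cat("  ", x$note, "\n")
  invisible(x)
}
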