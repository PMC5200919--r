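#' Read and write dosage matrices as TSV
#'
#' The dosage TSV has one row per sample with columns `sample_id`,
#' `phenotype` and one 0/1/2 column per SNP (`NA` for missing). SNP
#' metadata (chromosome, position, alleles) travels in a companion SNP
#' table written by [write_snp_table()].
#'
#' @param data A [genotype_dataset()].
#' @param path Output/input path of the dosage TSV.
#' @param snp_path Optional path of the companion SNP table; when absent on
#'   read, placeholder positions (single chromosome, SNP order) are used.
#' @return `write_dosage_tsv()` returns `path` invisibly;
#'   `read_dosage_tsv()` returns a [genotype_dataset()].
#' @export
write_dosage_tsv <- function(data, path, snp_path = NULL) {
  stopifnot(inherits(data, "genotype_dataset"))
  df <- data.frame(sample_id = data$samples$sample_id,
                   phenotype = data$samples$phenotype,
                   data$geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  if (!is.null(snp_path)) write_snp_table(data$snps, snp_path)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path, snp_path = NULL) {
  df <- data.table::fread(path, sep = "\t", na.strings = "NA",
                          data.table = FALSE)
  samples <- data.frame(sample_id = as.character(df$sample_id),
                        phenotype = as.integer(df$phenotype),
                        stringsAsFactors = FALSE)
  geno <- as.matrix(df[, -(1:2), drop = FALSE])
  snps <- if (!is.null(snp_path)) read_snp_table(snp_path) else
    data.frame(snp_id = colnames(geno), chrom = "chr0",
               pos = seq_len(ncol(geno)), stringsAsFactors = FALSE)
  snps <- snps[match(colnames(geno), snps$snp_id), , drop = FALSE]
  d <- genotype_dataset(geno, samples, snps)
  if (is.null(d$snps$maf)) d$snps$maf <- .snp_maf(d$geno)
  d
}

#' @rdname write_dosage_tsv
#' @param snps A SNP metadata table.
#' @export
write_snp_table <- function(snps, path) {
  data.table::fwrite(snps, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_snp_table <- function(path) {
  data.table::fread(path, sep = "\t", na.strings = "NA",
                    data.table = FALSE)
}

#' Read and write PLINK text genotypes (.ped/.map)
#'
#' `write_plink()` emits the classic 6-column .ped (family and individual
#' id, parents 0, sex 0, phenotype coded 1 = control / 2 = case) followed
#' by two allele columns per SNP ("0 0" for missing), and a 4-column .map
#' (chromosome, SNP id, genetic distance 0, 1-based position).
#' `read_plink()` parses the pair back; the minor allele of each SNP is
#' the rarer observed allele (alphabetical order breaks ties) and dosages
#' count its copies.
#'
#' @param data A [genotype_dataset()] whose SNP table carries
#'   `minor_allele` / `major_allele` (defaults A/B are used otherwise).
#' @param prefix Path prefix; `.ped` and `.map` are appended.
#' @return `write_plink()` returns `prefix` invisibly; `read_plink()`
#'   returns a [genotype_dataset()].
#' @export
write_plink <- function(data, prefix) {
  stopifnot(inherits(data, "genotype_dataset"))
  snps <- data$snps
  minor <- if (!is.null(snps$minor_allele)) snps$minor_allele else
    rep("A", nrow(snps))
  major <- if (!is.null(snps$major_allele)) snps$major_allele else
    rep("B", nrow(snps))
  g <- data$geno
  n <- nrow(g); p <- ncol(g)
  al <- matrix("0", n, 2L * p)
  for (j in seq_len(p)) {
    gj <- g[, j]
    a1 <- ifelse(is.na(gj), "0", ifelse(gj >= 1, minor[j], major[j]))
    a2 <- ifelse(is.na(gj), "0", ifelse(gj == 2, minor[j], major[j]))
    al[, 2L * j - 1L] <- a1
    al[, 2L * j] <- a2
  }
  ped <- data.frame(fid = data$samples$sample_id,
                    iid = data$samples$sample_id,
                    pat = 0L, mat = 0L, sex = 0L,
                    pheno = data$samples$phenotype + 1L,
                    al, stringsAsFactors = FALSE)
  data.table::fwrite(ped, paste0(prefix, ".ped"), sep = " ",
                     col.names = FALSE, quote = FALSE)
  map <- data.frame(chrom = snps$chrom, snp_id = snps$snp_id, cm = 0L,
                    pos = snps$pos, stringsAsFactors = FALSE)
  data.table::fwrite(map, paste0(prefix, ".map"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  map <- data.table::fread(paste0(prefix, ".map"), header = FALSE,
                           data.table = FALSE)
  names(map) <- c("chrom", "snp_id", "cm", "pos")
  ped <- data.table::fread(paste0(prefix, ".ped"), header = FALSE,
                           data.table = FALSE,
                           colClasses = "character")
  p <- nrow(map)
  if (ncol(ped) != 6L + 2L * p)
    stop(".ped column count does not match the .map SNP count")
  samples <- data.frame(sample_id = ped[[2]],
                        phenotype = as.integer(ped[[6]]) - 1L,
                        stringsAsFactors = FALSE)
  geno <- matrix(NA_integer_, nrow(ped), p)
  minor <- major <- character(p)
  for (j in seq_len(p)) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    obs <- c(a1, a2)
    obs <- obs[obs != "0"]
    alleles <- sort(unique(obs))
    if (length(alleles) == 0) alleles <- c("A", "B")
    if (length(alleles) == 1) alleles <- c(alleles, alleles)
    cnt <- c(sum(obs == alleles[1]), sum(obs == alleles[2]))
    minor[j] <- if (cnt[1] <= cnt[2]) alleles[1] else alleles[2]
    major[j] <- if (cnt[1] <= cnt[2]) alleles[2] else alleles[1]
    d <- (a1 == minor[j]) + (a2 == minor[j])
    d[a1 == "0" | a2 == "0"] <- NA
    geno[, j] <- as.integer(d)
  }
  snps <- data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                     minor_allele = minor, major_allele = major,
                     stringsAsFactors = FALSE)
  snps$maf <- .snp_maf(geno)
  snps$call_rate <- .snp_call_rate(geno)
  d <- genotype_dataset(geno, samples, snps)
  d
}

#' Read and write gene coordinates as BED
#'
#' Gene bodies are stored 0-based half-open in BED with the gene id in the
#' name column; reading restores the `gene_id`, `chrom`, `start`, `end`
#' table used by [map_snps_to_genes()].
#'
#' @param genes Gene table with `gene_id`, `chrom`, `start`, `end`.
#' @param path BED file path.
#' @return `write_gene_bed()` returns `path` invisibly; `read_gene_bed()`
#'   returns the gene table.
#' @export
write_gene_bed <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  names(gr) <- genes$gene_id
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_gene_bed
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(gene_id = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Read and write pathway gene sets in GMT format
#'
#' One pathway per line: name, description (`"na"` on write), then the
#' member gene ids, tab-separated.
#'
#' @param pathways Named list of gene-id vectors.
#' @param path GMT file path.
#' @return `write_gmt()` returns `path` invisibly; `read_gmt()` a named
#'   list of gene-id vectors.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm)
    paste(c(nm, "na", pathways[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Read and write two-column edge/annotation TSV tables
#'
#' @param df Data frame to write.
#' @param path File path.
#' @return The data frame (read) or `path` invisibly (write).
#' @export
write_edge_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_tsv
#' @export
read_edge_tsv <- function(path) {
  data.table::fread(path, sep = "\t", data.table = FALSE)
}

#' Read and write a gene ontology in OBO format
#'
#' A minimal OBO 1.2 subset: `[Term]` stanzas with `id`, `name`,
#' `namespace` and `is_a` tags. Namespaces are stored internally as
#' `BP`/`CC`/`MF` and written with the standard long names.
#'
#' @param onto A [go_ontology()].
#' @param path OBO file path.
#' @return `write_obo()` returns `path` invisibly; `read_obo()` a
#'   [go_ontology()].
#' @export
write_obo <- function(onto, path) {
  stopifnot(inherits(onto, "go_ontology"))
  long <- c(BP = "biological_process", CC = "cellular_component",
            MF = "molecular_function")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  par <- onto$parents
  name <- setNames(onto$terms$name, onto$terms$term_id)
  for (i in seq_len(nrow(onto$terms))) {
    t <- onto$terms$term_id[i]
    lines <- c("[Term]", paste0("id: ", t),
               paste0("name: ", onto$terms$name[i]),
               paste0("namespace: ", long[[onto$terms$namespace[i]]]))
    for (p in par[[t]])
      lines <- c(lines, sprintf("is_a: %s ! %s", p, name[[p]]))
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}

#' @rdname write_obo
#' @export
read_obo <- function(path) {
  short <- c(biological_process = "BP", cellular_component = "CC",
             molecular_function = "MF")
  lines <- readLines(path)
  in_term <- FALSE
  terms <- list(); edges <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) {
      terms[[length(terms) + 1L]] <<- data.frame(
        term_id = cur$id, name = cur$name %||% cur$id,
        namespace = short[[cur$namespace %||% "biological_process"]],
        stringsAsFactors = FALSE)
      for (p in cur$parents)
        edges[[length(edges) + 1L]] <<- data.frame(child = cur$id,
                                                   parent = p)
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(parents = character())
                          in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || ln == "") next
    if (startsWith(ln, "id: ")) cur$id <- sub("^id: ", "", ln)
    else if (startsWith(ln, "name: ")) cur$name <- sub("^name: ", "", ln)
    else if (startsWith(ln, "namespace: "))
      cur$namespace <- sub("^namespace: ", "", ln)
    else if (startsWith(ln, "is_a: "))
      cur$parents <- c(cur$parents,
                       sub("\\s*!.*$", "", sub("^is_a: ", "", ln)))
  }
  flush()
  go_ontology(do.call(rbind, terms),
              if (length(edges)) do.call(rbind, edges) else
                data.frame(child = character(), parent = character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write the planted-truth record as JSON
#'
#' @param truth Truth record from [generate_genotypes()].
#' @param path JSON file path.
#' @return `write_truth_json()` returns `path` invisibly;
#'   `read_truth_json()` the truth list.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns",
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$planted_pairs <- as.data.frame(x$planted_pairs,
                                   stringsAsFactors = FALSE)
  x$beta_table <- as.data.frame(x$beta_table, stringsAsFactors = FALSE)
  x
}
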