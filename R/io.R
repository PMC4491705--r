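## Readers and writers for the fixture / result formats, interval overlap,
## and YAML configuration.  Internal coordinates are 1-based inclusive
## (GTF convention); BED files on disk are 0-based half-open and converted
## at the boundary by rtracklayer.

.write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", provenance), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE, ...)
  df
}

#' Write simulated data as plain-text fixtures
#'
#' Emits `snps.tsv`, `counts_alleles.tsv`, `counts_genes.tsv`,
#' `genes.gtf`, `truth.tsv`, `labels.tsv` and `config.yaml` into a
#' directory.  Each TSV carries a `#`-prefixed provenance line recording
#' the seed; everything round-trips losslessly through the readers.
#'
#' @param sim A `ctrex_sim` object from [simulate_ase()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixtures <- function(sim, dir) {
  stopifnot(inherits(sim, "ctrex_sim"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  prov <- paste0("ctrex fixture; seed=", sim$config$seed)
  .write_tsv(sim$snps, file.path(dir, "snps.tsv"), prov)
  .write_tsv(sim$counts, file.path(dir, "counts_alleles.tsv"), prov)
  .write_tsv(sim$gene_counts, file.path(dir, "counts_genes.tsv"), prov)
  .write_tsv(sim$truth, file.path(dir, "truth.tsv"), prov)
  .write_tsv(sim$labels, file.path(dir, "labels.tsv"), prov)
  write_gene_models(sim$truth, file.path(dir, "genes.gtf"))
  cfg <- sim$config
  cfg$chromosomes <- as.list(as.data.frame(cfg$chromosomes))
  cfg$label_table <- as.list(as.data.frame(cfg$label_table))
  cfg$depth_factors <- as.list(cfg$depth_factors)
  cfg$mode_proportions <- as.list(cfg$mode_proportions)
  cfg$misexpr_status_probs <- as.list(cfg$misexpr_status_probs)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a SNP site table
#'
#' @param path TSV with columns `chrom`, `pos`, `ref_P`, `alt_B` and
#'   per-sample per-allele counts; `#` lines are comments.
#' @return Data frame.
#' @export
read_snp_table <- function(path) {
  df <- .read_tsv(path, colClasses = c(chrom = "character"))
  need <- c("chrom", "pos", "ref_P", "alt_B", "parentP_P", "parentP_B",
            "parentB_P", "parentB_B", "hybF_P", "hybF_B",
            "hybS_P", "hybS_B")
  .check_columns(df, need, path)
  if (anyDuplicated(df[c("chrom", "pos")]))
    stop("duplicate SNP positions in ", path)
  df
}

#' Read a gene-level allele-count table
#'
#' @param path TSV as written by [write_fixtures()] (`counts_alleles.tsv`).
#' @return Data frame.
#' @export
read_allele_counts <- function(path) {
  df <- .read_tsv(path, colClasses = c(chrom = "character"))
  .check_columns(df, c("gene_id", "chrom", "start", "end",
                       names(.CTREX_SLOTS)), path)
  .check_genes(df, path)
  df
}

#' Read a replicate-level gene count table
#'
#' @param path TSV with `gene_id`, `chrom`, `start`, `end` and replicate
#'   columns `P_1 ... HS_2`.
#' @return Data frame.
#' @export
read_gene_counts <- function(path) {
  df <- .read_tsv(path, colClasses = c(chrom = "character"))
  .check_columns(df, c("gene_id", "P_1", "P_2", "B_1", "B_2",
                       "HF_1", "HF_2", "HS_1", "HS_2"), path)
  .check_genes(df, path)
  df
}

#' Read a gene -> functional label table
#'
#' @param path TSV with columns `gene_id`, `label`.
#' @return Data frame (one row per gene/label pair).
#' @export
read_labels <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  .check_columns(df, c("gene_id", "label"), path)
  df
}

#' Read a simulation truth table
#'
#' @param path `truth.tsv` as written by [write_fixtures()].
#' @return Data frame.
#' @export
read_truth <- function(path) {
  df <- .read_tsv(path, colClasses = c(chrom = "character",
                                       delta_cis = "numeric",
                                       delta_trans = "numeric",
                                       ratio_shift = "numeric"))
  .check_columns(df, c("gene_id", "chrom", "start", "end", "true_mode"),
                 path)
  df
}

.check_columns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  invisible(df)
}

.check_genes <- function(df, path) {
  if (anyDuplicated(df$gene_id))
    stop(path, ": duplicate gene_id(s)")
  if (all(c("start", "end") %in% names(df)) && any(df$end < df$start)) {
    bad <- which(df$end < df$start)
    stop(path, ": end < start for gene(s) ",
         paste(utils::head(df$gene_id[bad], 5), collapse = ", "))
  }
  invisible(df)
}

#' Read gene models from a GTF file
#'
#' Uses rtracklayer; only `gene`-type records (or all records when no type
#' column is present) are kept.  GTF coordinates are 1-based inclusive.
#'
#' @param path GTF file.
#' @return Data frame with `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) == "gene"]
  df <- data.frame(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  .check_genes(df, path)
  df
}

#' Write gene models to a GTF file
#'
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    type = "gene", gene_id = genes$gene_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read genomic regions from a BED file
#'
#' BED intervals are 0-based half-open on disk; rtracklayer converts them
#' to 1-based inclusive coordinates on import.
#'
#' @param path BED file.
#' @return Data frame with `chrom`, `start`, `end` and `name` (region
#'   index when absent).
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- if ("name" %in% names(S4Vectors::mcols(gr)))
    as.character(gr$name) else paste0("region", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             name = nm, stringsAsFactors = FALSE)
}

#' Write regions to a BED file
#'
#' @param regions Data frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `name`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start, regions$end))
  if ("name" %in% names(regions)) gr$name <- regions$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Genes overlapping genomic regions
#'
#' A gene belongs to a region when its span overlaps the region by at
#' least one base pair; `within = TRUE` requires full containment.
#'
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end`.
#' @param regions Data frame with `chrom`, `start`, `end` and `name`
#'   (1-based inclusive, e.g. from [read_regions_bed()]).
#' @param within Require the gene to lie entirely inside the region.
#' @return Data frame with one row per (region, gene) pair.
#' @export
genes_in_regions <- function(genes, regions, within = FALSE) {
  if (!"name" %in% names(regions))
    regions$name <- paste0("region", seq_len(nrow(regions)))
  gr_g <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  gr_r <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start, regions$end))
  hits <- GenomicRanges::findOverlaps(
    gr_g, gr_r, type = if (within) "within" else "any")
  data.frame(
    region = regions$name[S4Vectors::subjectHits(hits)],
    gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE)
}

#' Read a pipeline configuration from YAML
#'
#' Reconstructs a [sim_config()] object (validated) from a
#' `config.yaml` written by [write_fixtures()].
#'
#' @param path YAML file.
#' @return A `ctrex_sim_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_config(
    n_genes = y$n_genes,
    chromosomes = as.data.frame(y$chromosomes,
                                stringsAsFactors = FALSE),
    mode_proportions = unlist(y$mode_proportions),
    cis_effect_log2 = y$cis_effect_log2,
    trans_effect_log2 = y$trans_effect_log2,
    baseline_log_mean = y$baseline_log_mean,
    baseline_log_sd = y$baseline_log_sd,
    mean_snp_reads = y$mean_snp_reads,
    effect_signs = y$effect_signs,
    overdispersion = y$overdispersion,
    depth_factors = unlist(y$depth_factors),
    misexpr_fraction_sterile = y$misexpr_fraction_sterile,
    misexpr_fraction_fertile = y$misexpr_fraction_fertile,
    misexpr_fold_log2 = y$misexpr_fold_log2,
    misexpr_status_probs = unlist(y$misexpr_status_probs),
    ratio_shift_fraction = y$ratio_shift_fraction,
    ratio_shift_log2 = y$ratio_shift_log2,
    label_table = as.data.frame(y$label_table, stringsAsFactors = FALSE),
    mean_snps_per_gene = y$mean_snps_per_gene,
    seed = y$seed)
}
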