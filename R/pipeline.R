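## End-to-end pipeline: simulate -> fixture files -> fixed-SNP aggregation
## -> cis/trans classification -> misexpression + enrichment -> hybrid
## ratio comparison -> report.  Deterministic given the config seed; all
## thresholds are echoed into the report.

#' Run the full analysis pipeline on simulated data
#'
#' Generates data from `config`, writes the fixture files, then runs every
#' analysis stage and writes result tables plus a YAML report into
#' `outdir`.  Output is deterministic given `config$seed` (rtracklayer
#' stamps GTF/BED headers with a date comment; all other content is
#' byte-stable).
#'
#' @param config A [sim_config()] object.
#' @param outdir Output directory (created if needed).
#' @param hybrid Hybrid used for autosomal cis/trans calls (default
#'   fertile, avoiding sterility-specific effects).
#' @param q_cistrans Significance threshold for the divergence tests
#'   (default 0.005).
#' @param q_strict Stricter reporting threshold for the ratio comparison
#'   (default 0.001).
#' @param alpha_de FDR threshold for differential expression (default
#'   0.05).
#' @param window_bp,min_genes Cluster-detection parameters (defaults
#'   150000 bp and 3 genes).
#' @param qtl_bed Optional BED file of QTL regions; when given, genes
#'   uniquely misexpressed in the sterile hybrid are intersected with the
#'   regions.
#' @return Invisibly, a list with all stage outputs and the report.
#' @export
run_pipeline <- function(config, outdir,
                         hybrid = c("fertile", "sterile"),
                         q_cistrans = 0.005, q_strict = 0.001,
                         alpha_de = 0.05,
                         window_bp = 150000, min_genes = 3,
                         qtl_bed = NULL) {
  hybrid <- match.arg(hybrid)
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop("cannot create directory: ", outdir)
  log_stage <- function(stage, n_in, n_out)
    message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))

  sim <- simulate_ase(config)
  write_fixtures(sim, file.path(outdir, "fixtures"))
  x_chroms <- config$chromosomes$name[config$chromosomes$is_x]

  ## allele counting funnel: fixed SNPs -> aggregated genes -> tested genes
  fixed <- call_fixed_snps(sim$snps)
  log_stage("fixed_snps", nrow(sim$snps), nrow(fixed))
  gene_models <- sim$truth[c("gene_id", "chrom", "start", "end")]
  prepared <- suppressWarnings(
    zero_adjust(normalize_counts(
      aggregate_allele_counts(fixed, gene_models))))
  log_stage("aggregate", nrow(gene_models), nrow(prepared))

  reg <- classify_regulation(prepared, hybrid = hybrid,
                             q_threshold = q_cistrans,
                             x_chroms = x_chroms)
  reg_sum <- summarize_regulation(reg)
  .write_tsv(reg, file.path(outdir, "regulatory_calls.tsv"))
  log_stage("classify", nrow(prepared), nrow(reg))

  mis <- misexpression_calls(sim$gene_counts, alpha = alpha_de)
  sets <- unique_sets(mis)
  enr <- label_enrichment(sets$fertile_unique, sets$sterile_unique,
                          sim$labels)
  chr_tab <- chromosome_table(mis)
  .write_tsv(mis, file.path(outdir, "misexpression_calls.tsv"))
  .write_tsv(enr, file.path(outdir, "enrichment.tsv"))
  .write_tsv(chr_tab, file.path(outdir, "chromosome_table.tsv"))
  log_stage("misexpression", nrow(sim$gene_counts), nrow(mis))

  cmp <- compare_hybrid_ratios(prepared, x_chroms = x_chroms)
  ratio_sum <- summarize_hybrid_ratios(
    cmp, q_thresholds = c(q_cistrans, q_strict))
  chrom_lengths <- setNames(config$chromosomes$length,
                            config$chromosomes$name)
  dens <- density_and_clusters(ratio_sum$comparisons, chrom_lengths,
                               window_bp = window_bp,
                               min_genes = min_genes)
  .write_tsv(ratio_sum$comparisons,
             file.path(outdir, "ratio_comparisons.tsv"))
  if (nrow(dens$clusters) > 0)
    write_regions_bed(dens$clusters, file.path(outdir, "clusters.bed"))
  log_stage("compare", nrow(prepared), nrow(cmp))

  qtl <- NULL
  if (!is.null(qtl_bed)) {
    regions <- read_regions_bed(qtl_bed)
    sterile_genes <- gene_models[
      gene_models$gene_id %in% sets$sterile_unique, , drop = FALSE]
    qtl <- genes_in_regions(sterile_genes, regions)
    .write_tsv(qtl, file.path(outdir, "qtl_overlap.tsv"))
  }

  report <- list(
    thresholds = list(q_cistrans = q_cistrans, q_strict = q_strict,
                      alpha_de = alpha_de, min_snp_reads = 3,
                      min_gene_reads = 20, min_de_reads = 10,
                      window_bp = window_bp, min_genes = min_genes,
                      hybrid_for_cistrans = hybrid),
    seed = config$seed,
    funnel = list(n_snps = nrow(sim$snps), n_fixed_snps = nrow(fixed),
                  n_genes_simulated = config$n_genes,
                  n_genes_ase_tested = nrow(prepared),
                  n_genes_autosomal_compared = nrow(cmp)),
    regulation = list(
      counts = as.list(reg_sum$counts),
      cis_n = reg_sum$cis_n, trans_n = reg_sum$trans_n,
      cis_fraction = reg_sum$cis_fraction,
      cis_vs_trans_p = if (is.null(reg_sum$cis_vs_trans)) NA else
        reg_sum$cis_vs_trans$p.value,
      counting_rule = reg_sum$counting_rule),
    misexpression = list(counts = as.list(sets$counts),
                         dispersion = attr(mis, "dispersion")),
    ratios = list(r = ratio_sum$r, r_p = ratio_sum$r_p,
                  frac_significant = as.list(ratio_sum$frac_significant),
                  n_top = length(ratio_sum$top_genes),
                  n_clusters = nrow(dens$clusters)))
  yaml::write_yaml(report, file.path(outdir, "report.yaml"))

  invisible(list(sim = sim, prepared = prepared, regulation = reg,
                 regulation_summary = reg_sum, misexpression = mis,
                 sets = sets, enrichment = enr,
                 chromosome_table = chr_tab, ratio_summary = ratio_sum,
                 density = dens, qtl_overlap = qtl, report = report))
}
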