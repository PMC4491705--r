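## Fixed-SNP identification and gene-level allele-count preparation:
## filter (raw) -> normalize -> zero-adjust.  Filtering precedes depth
## scaling so the read-support threshold is independent of library size.

#' Identify fixed SNP sites between the parental species
#'
#' A site is fixed when each parental sample is represented by a single,
#' different allele with at least `min_reads` reads supporting each parent.
#' With biallelic sites coded as P-allele / B-allele count pairs, this means
#' the P parent carries only the P allele (>= `min_reads` reads, zero on the
#' B allele) and conversely for the B parent.
#'
#' @param snps SNP site table as produced by [simulate_ase()] or
#'   [read_snp_table()]: columns `chrom`, `pos`, `ref_P`, `alt_B`,
#'   `parentP_P`, `parentP_B`, `parentB_P`, `parentB_B`, `hybF_P`,
#'   `hybF_B`, `hybS_P`, `hybS_B`.
#' @param min_reads Minimum supporting reads per parent (default 3).
#' @return The subset of rows that pass; possibly empty.
#' @export
call_fixed_snps <- function(snps, min_reads = 3) {
  required <- c("chrom", "pos", "parentP_P", "parentP_B",
                "parentB_P", "parentB_B")
  if (!all(required %in% names(snps)))
    stop("missing SNP table columns: ",
         paste(setdiff(required, names(snps)), collapse = ", "))
  keep <- snps$parentP_P >= min_reads & snps$parentP_B == 0 &
    snps$parentB_B >= min_reads & snps$parentB_P == 0
  out <- snps[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate fixed-SNP allele counts to gene level
#'
#' Sums allele-resolved read counts over all fixed SNP sites falling within
#' each gene's span (1-based inclusive coordinates).  Hybrid reads are
#' assigned to a parent of origin by allele identity.  Genes whose combined
#' parental support falls below `min_gene_reads` are dropped.  A SNP
#' overlapping several genes is counted toward every one of them, with a
#' warning naming the affected genes.
#'
#' @param snps Fixed SNP sites (see [call_fixed_snps()]).
#' @param genes Gene models: columns `gene_id`, `chrom`, `start`, `end`.
#' @param min_gene_reads Minimum `parent_P + parent_B` raw reads (default
#'   20, inclusive).
#' @return Gene-level allele-count table with columns `gene_id`, `chrom`,
#'   `start`, `end`, `n_snps` and the six raw count slots.
#' @export
aggregate_allele_counts <- function(snps, genes, min_gene_reads = 20) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_ids in gene models")
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  gr_snps <- GenomicRanges::GRanges(
    snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(gr_snps, gr_genes)
  sh <- S4Vectors::queryHits(hits)
  gh <- S4Vectors::subjectHits(hits)
  multi <- unique(sh[duplicated(sh)])
  if (length(multi) > 0) {
    affected <- unique(genes$gene_id[gh[sh %in% multi]])
    warning(length(multi), " SNP(s) overlap multiple genes; counted ",
            "toward each (genes: ",
            paste(utils::head(affected, 5), collapse = ", "),
            if (length(affected) > 5) ", ..." else "", ")")
  }
  slots <- c(parent_P = "parentP_P", parent_B = "parentB_B",
             hybF_P = "hybF_P", hybF_B = "hybF_B",
             hybS_P = "hybS_P", hybS_B = "hybS_B")
  sums <- vapply(slots, function(col) {
    v <- integer(nrow(genes))
    if (length(sh) > 0) {
      agg <- rowsum(as.numeric(snps[[col]][sh]), gh)
      v[as.integer(rownames(agg))] <- as.integer(agg[, 1])
    }
    v
  }, integer(nrow(genes)))
  if (nrow(genes) == 1L)
    sums <- matrix(sums, nrow = 1, dimnames = list(NULL, names(slots)))
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = genes$start, end = genes$end,
                    n_snps = tabulate(gh, nbins = nrow(genes)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(sums))
  keep <- out$parent_P + out$parent_B >= min_gene_reads
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Depth-normalize gene-level allele counts
#'
#' Scales each sample's counts by (median size factor / sample size
#' factor) and rounds to the nearest integer (half away from zero) so the
#' exact tests downstream remain valid.  By default the per-sample size
#' factor is the median-of-ratios estimator (the median across genes of
#' the sample count over the gene's geometric mean across samples), which
#' measures sequencing depth robustly even when many genes are genuinely
#' differentially expressed; raw per-sample totals can be supplied
#' instead via `library_sizes`.
#'
#' @param counts Output of [aggregate_allele_counts()].
#' @param library_sizes Optional named vector (`parent_P`, `parent_B`,
#'   `hybrid_fertile`, `hybrid_sterile`) of library sizes or size
#'   factors; all entries must be positive.
#' @return `counts` with added `norm_*` columns.
#' @export
normalize_counts <- function(counts, library_sizes = NULL) {
  if (is.null(library_sizes)) {
    m <- cbind(parent_P = counts$parent_P,
               parent_B = counts$parent_B,
               hybrid_fertile = counts$hybF_P + counts$hybF_B,
               hybrid_sterile = counts$hybS_P + counts$hybS_B)
    pos <- rowSums(m > 0) == ncol(m)
    if (sum(pos) >= 10) {
      geo <- exp(rowMeans(log(m[pos, , drop = FALSE])))
      library_sizes <- apply(m[pos, , drop = FALSE] / geo, 2, median)
    } else {
      library_sizes <- colSums(m)   # too few genes for ratio medians
    }
  }
  if (!all(.CTREX_SAMPLES %in% names(library_sizes)))
    stop("library_sizes must be named for all four samples")
  if (any(library_sizes[.CTREX_SAMPLES] <= 0))
    stop("library sizes must be positive")
  scale <- median(library_sizes[.CTREX_SAMPLES]) /
    library_sizes[.CTREX_SAMPLES]
  round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  for (slot in names(.CTREX_SLOTS)) {
    counts[[paste0("norm_", slot)]] <-
      as.integer(round_half_away(counts[[slot]] *
                                   scale[.CTREX_SLOTS[[slot]]]))
  }
  attr(counts, "library_sizes") <- library_sizes[.CTREX_SAMPLES]
  counts
}

#' Adjust zero counts to one
#'
#' Every zero normalized slot becomes 1 so that the exact tests are
#' defined; adjusted slots are flagged in `zadj_*` columns.
#'
#' @param counts Output of [normalize_counts()].
#' @return `counts` with zeros replaced and flags added.
#' @export
zero_adjust <- function(counts) {
  norm_cols <- paste0("norm_", names(.CTREX_SLOTS))
  if (!all(norm_cols %in% names(counts)))
    stop("run normalize_counts() first")
  for (slot in names(.CTREX_SLOTS)) {
    cn <- paste0("norm_", slot)
    flag <- counts[[cn]] == 0L
    counts[[cn]][flag] <- 1L
    counts[[paste0("zadj_", slot)]] <- flag
  }
  counts
}

#' Prepare gene-level allele counts from a SNP table
#'
#' Convenience chain: [call_fixed_snps()] -> [aggregate_allele_counts()] ->
#' [normalize_counts()] -> [zero_adjust()].
#'
#' @inheritParams call_fixed_snps
#' @inheritParams aggregate_allele_counts
#' @inheritParams normalize_counts
#' @return Fully prepared gene-level table (raw, normalized and flag
#'   columns).
#' @export
prepare_allele_counts <- function(snps, genes, min_reads = 3,
                                  min_gene_reads = 20,
                                  library_sizes = NULL) {
  fixed <- call_fixed_snps(snps, min_reads = min_reads)
  agg <- aggregate_allele_counts(fixed, genes,
                                 min_gene_reads = min_gene_reads)
  zero_adjust(normalize_counts(agg, library_sizes = library_sizes))
}
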