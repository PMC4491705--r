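## Fertile-vs-sterile comparison of allelic expression ratios across
## autosomal genes: per-gene Fisher tests, genome-wide correlation of log2
## ratios, fold-change ranking, reversal detection, per-chromosome density
## and positional clustering of flagged genes.

#' Per-gene comparison of allelic ratios between hybrids
#'
#' For each autosomal gene, tests the 2x2 table
#' `[fertile P, fertile B; sterile P, sterile B]` with Fisher's exact test
#' and derives allelic ratios (P allele / B allele) from the normalized,
#' zero-adjusted counts, so log2 ratios are always finite.  X-linked genes
#' are excluded: the paternal allele is absent so no allelic ratio exists.
#'
#' @param counts Prepared gene-level allele counts
#'   ([prepare_allele_counts()]).
#' @param x_chroms Chromosome names treated as X-linked.
#' @return Data frame with one row per autosomal gene: ratios, log2
#'   ratios, `fold_change` (`>= 1`), `p`, `reversal` flag and
#'   `reversal_magnitude` (`|log2 rF - log2 rS|`).
#' @export
compare_hybrid_ratios <- function(counts, x_chroms = "X") {
  need <- paste0("norm_", names(.CTREX_SLOTS))
  if (!all(need %in% names(counts)))
    stop("counts must be normalized and zero-adjusted")
  auto <- counts[!(counts$chrom %in% x_chroms), , drop = FALSE]
  if (nrow(auto) == 0) stop("no autosomal genes to compare")
  rf <- auto$norm_hybF_P / auto$norm_hybF_B
  rs <- auto$norm_hybS_P / auto$norm_hybS_B
  l2f <- log2(rf); l2s <- log2(rs)
  p <- .fisher_p(auto$norm_hybF_P, auto$norm_hybF_B,
                 auto$norm_hybS_P, auto$norm_hybS_B)
  data.frame(
    gene_id = auto$gene_id, chrom = auto$chrom,
    start = auto$start, end = auto$end,
    ratio_fertile = rf, ratio_sterile = rs,
    log2_fertile = l2f, log2_sterile = l2s,
    fold_change = 2^abs(l2f - l2s),
    p = p,
    reversal = sign(l2f) != sign(l2s) & l2f != 0 & l2s != 0,
    reversal_magnitude = abs(l2f - l2s),
    stringsAsFactors = FALSE
  )
}

#' Genome-wide summary of hybrid allelic-ratio differences
#'
#' Pearson correlation of log2 allelic ratios between the hybrids,
#' BH q-values over the per-gene Fisher p-values, the fraction of genes
#' significant at each threshold, the top `top_pct` percent of genes by
#' fold change (`ceiling(pct/100 * N)` genes, ties broken by gene id) and
#' the ten largest reversals.
#'
#' @param comparisons Output of [compare_hybrid_ratios()] (>= 3 rows).
#' @param q_thresholds Significance thresholds reported (default 0.005 and
#'   0.001, strict inequality).
#' @param top_pct Percentage for the fold-change ranking (default 1).
#' @param n_reversals Number of top reversals to report (default 10).
#' @return List with `r`, `r_p`, `comparisons` (with `q` and `top_flag`
#'   columns added), `frac_significant`, `top_genes` and `top_reversals`.
#' @export
summarize_hybrid_ratios <- function(comparisons,
                                    q_thresholds = c(0.005, 0.001),
                                    top_pct = 1, n_reversals = 10) {
  stopifnot(nrow(comparisons) >= 3)
  ct <- pearson_r(comparisons$log2_fertile, comparisons$log2_sterile)
  comparisons$q <- bh_fdr(comparisons$p)
  frac <- vapply(q_thresholds,
                 function(th) mean(comparisons$q < th), numeric(1))
  names(frac) <- paste0("q<", q_thresholds)
  n_top <- ceiling(top_pct / 100 * nrow(comparisons))
  ord <- order(-comparisons$fold_change, comparisons$gene_id)
  top_idx <- ord[seq_len(n_top)]
  comparisons$top_flag <- FALSE
  comparisons$top_flag[top_idx] <- TRUE
  rev_pool <- comparisons[comparisons$reversal, , drop = FALSE]
  rev_ord <- order(-rev_pool$reversal_magnitude, rev_pool$gene_id)
  top_rev <- rev_pool[utils::head(rev_ord, n_reversals), , drop = FALSE]
  list(r = ct$estimate, r_p = ct$p.value,
       comparisons = comparisons,
       frac_significant = frac,
       top_genes = comparisons$gene_id[top_idx],
       top_reversals = top_rev)
}

#' Chromosomal density and clustering of flagged genes
#'
#' Computes, per chromosome, the density of flagged genes per megabase and
#' pairwise two-proportion Z-tests of flagged/total genes between
#' chromosomes, then reports positional clusters: maximal runs of at least
#' `min_genes` flagged genes whose consecutive midpoint gaps are all
#' `<= window_bp`.
#'
#' @param comparisons Output of [summarize_hybrid_ratios()]`$comparisons`
#'   or any data frame with `gene_id`, `chrom`, `start`, `end` and a
#'   logical flag column.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param flag Name of the logical column marking genes of interest
#'   (default `"top_flag"`).
#' @param window_bp Maximum gap between consecutive flagged genes within a
#'   cluster (default 150000).
#' @param min_genes Minimum flagged genes per cluster (default 3).
#' @return List with `density` (per-chromosome data frame),
#'   `pairwise` (Z-tests between chromosomes) and `clusters`
#'   (chrom, start, end, n_genes, span_bp, gene ids).
#' @export
density_and_clusters <- function(comparisons, chrom_lengths,
                                 flag = "top_flag", window_bp = 150000,
                                 min_genes = 3) {
  stopifnot(flag %in% names(comparisons))
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  fl <- comparisons[[flag]]
  chroms <- intersect(names(chrom_lengths), unique(comparisons$chrom))
  dens <- do.call(rbind, lapply(chroms, function(cc) {
    i <- comparisons$chrom == cc
    data.frame(chrom = cc, n_genes = sum(i), n_flagged = sum(fl & i),
               length_mb = chrom_lengths[[cc]] / 1e6,
               density_per_mb = sum(fl & i) / (chrom_lengths[[cc]] / 1e6),
               stringsAsFactors = FALSE)
  }))
  pairwise <- NULL
  if (length(chroms) >= 2) {
    combs <- utils::combn(chroms, 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
      c1 <- combs[1, j]; c2 <- combs[2, j]
      i1 <- dens$chrom == c1; i2 <- dens$chrom == c2
      tst <- two_prop_z(dens$n_flagged[i1], dens$n_genes[i1],
                        dens$n_flagged[i2], dens$n_genes[i2])
      data.frame(chrom1 = c1, chrom2 = c2, z = tst$statistic,
                 p = tst$p.value, stringsAsFactors = FALSE)
    }))
  }
  clusters <- .find_clusters(comparisons[fl, , drop = FALSE],
                             window_bp, min_genes)
  list(density = dens, pairwise = pairwise, clusters = clusters)
}

## maximal runs of flagged genes with consecutive midpoint gaps <= window
.find_clusters <- function(flagged, window_bp, min_genes) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_genes = integer(0),
                      span_bp = integer(0), gene_ids = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(flagged) == 0) return(empty)
  out <- list()
  for (cc in unique(flagged$chrom)) {
    sub <- flagged[flagged$chrom == cc, , drop = FALSE]
    mid <- (sub$start + sub$end) / 2
    ord <- order(mid, sub$gene_id)
    sub <- sub[ord, , drop = FALSE]; mid <- mid[ord]
    run_id <- cumsum(c(1, diff(mid) > window_bp))
    for (r in unique(run_id)) {
      i <- run_id == r
      if (sum(i) < min_genes) next
      out[[length(out) + 1]] <- data.frame(
        chrom = cc, start = min(sub$start[i]), end = max(sub$end[i]),
        n_genes = sum(i),
        span_bp = round(max(mid[i]) - min(mid[i])),
        gene_ids = paste(sub$gene_id[i], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}
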