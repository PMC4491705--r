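## Hybrid misexpression: differential expression between each hybrid and
## each parent, additive vs transgressive classification, uniquely
## misexpressed sets, functional-label enrichment, per-chromosome tables
## and the mapping-bias sanity check.

.DE_PAIRS <- list(
  P_vs_B = c("P", "B"),
  HF_vs_P = c("HF", "P"), HF_vs_B = c("HF", "B"),
  HS_vs_P = c("HS", "P"), HS_vs_B = c("HS", "B"))

#' Method-of-moments overdispersion estimate
#'
#' Pools replicate pairs across genes and conditions:
#' `phi = max(0, sum(var - mean) / sum(mean^2))` under the
#' negative-binomial variance function `mu + phi mu^2`.
#'
#' @param mat Numeric matrix, one row per gene, replicate columns grouped
#'   in consecutive pairs (e.g. `P_1,P_2,B_1,B_2,...`).
#' @return Non-negative dispersion estimate.
#' @export
estimate_dispersion <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) %% 2 != 0) stop("expected replicate pairs of columns")
  num <- 0; den <- 0
  for (j in seq(1, ncol(mat), by = 2)) {
    m <- rowMeans(mat[, j:(j + 1), drop = FALSE])
    v <- (mat[, j] - mat[, j + 1])^2 / 2    # sample variance for n = 2
    keep <- m > 0
    num <- num + sum(v[keep] - m[keep])
    den <- den + sum(m[keep]^2)
  }
  if (den == 0) return(0)
  max(0, num / den)
}

#' Differential-expression p-value for two replicate pairs
#'
#' A conditional exact test on replicate-summed counts: given the total,
#' the count of condition A is binomial with null proportion equal to A's
#' share of the combined library size.  Overdispersion is absorbed
#' quasi-style by deflating both sums by `1 + dispersion * mean` before
#' testing.  This is a deliberately simple stand-in for a full
#' count-model DE engine; externally computed significance calls can be
#' supplied to [misexpression_calls()] instead.
#'
#' @param a,b Numeric vectors of replicate counts (typically length 2).
#' @param dispersion Negative-binomial dispersion phi (default 0).
#' @param lib_a,lib_b Library sizes of the two conditions (defaults equal).
#' @return Two-sided p-value in `[0, 1]`; 1 when both sums are zero.
#' @export
de_pvalue <- function(a, b, dispersion = 0, lib_a = 1, lib_b = 1) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  f <- 1 + dispersion * (sa + sb) / 2
  ka <- round(sa / f); kb <- round(sb / f)
  if (ka + kb == 0) return(1)
  p0 <- lib_a / (lib_a + lib_b)
  if (p0 <= 0 || p0 >= 1) return(1)
  .binom_p(ka, ka + kb, p0)
}

#' Classify hybrid expression relative to the parents
#'
#' A gene is misregulated in a hybrid when that hybrid differs
#' significantly from at least one parent.  Misregulated genes with
#' expression above both parental means are transgressive `over`, below
#' both `under`, and intermediate `additive`.  A hybrid mean exactly equal
#' to a parental mean while significant against the other parent is
#' classified additive with a warning.
#'
#' @param h,p,b Hybrid and parental mean expression (common scale).
#' @param sig_p,sig_b Logical: hybrid-vs-parent comparison significant?
#' @return Character vector in
#'   `{"not_misregulated", "additive", "over", "under"}`.
#' @export
classify_misexpression <- function(h, p, b, sig_p, sig_b) {
  mis <- sig_p | sig_b
  status <- rep("not_misregulated", length(h))
  over <- mis & h > pmax(p, b)
  under <- mis & h < pmin(p, b)
  status[mis] <- "additive"
  status[over] <- "over"
  status[under] <- "under"
  edge <- mis & (h == p | h == b)
  if (any(edge, na.rm = TRUE))
    warning(sum(edge), " significant gene(s) with hybrid mean exactly ",
            "equal to a parental mean; classified additive")
  status
}

#' Misexpression calls for both hybrids
#'
#' Runs the five pairwise DE comparisons (parent vs parent and each hybrid
#' vs each parent) on a replicate-level gene count table, FDR-corrects each
#' comparison across genes, and classifies each gene's status per hybrid.
#' Genes with fewer than `min_reads` in every sample are not tested
#' (the paper-style detectability filter).
#'
#' @param gene_counts Data frame with `gene_id`, `chrom` and replicate
#'   columns `P_1, P_2, B_1, B_2, HF_1, HF_2, HS_1, HS_2`.
#' @param alpha FDR threshold for DE significance (default 0.05).
#' @param dispersion Overdispersion; estimated from the data when NULL.
#' @param min_reads A gene is testable when at least one sample has this
#'   many mapped reads (default 10).
#' @param precomputed Optional data frame of externally computed q-values
#'   (columns `gene_id` plus any of `q_P_vs_B`, `q_HF_vs_P`, `q_HF_vs_B`,
#'   `q_HS_vs_P`, `q_HS_vs_B`); used in place of the built-in DE test.
#' @param lib_sizes Optional named condition depths (`P`, `B`, `HF`,
#'   `HS`) used for the library-size offset and the common expression
#'   scale; defaults to the observed condition totals.
#' @return Data frame with per-pair q-values, per-hybrid `status_*`,
#'   `both_sig_*` flags (significant against both parents), and
#'   `unique_to` in `{"none", "fertile", "sterile", "both"}` ("both" =
#'   shared misregulation).
#' @export
misexpression_calls <- function(gene_counts, alpha = 0.05,
                                dispersion = NULL, min_reads = 10,
                                precomputed = NULL, lib_sizes = NULL) {
  reps <- c("P_1", "P_2", "B_1", "B_2", "HF_1", "HF_2", "HS_1", "HS_2")
  stopifnot(all(c("gene_id", reps) %in% names(gene_counts)))
  mat <- as.matrix(gene_counts[reps])
  cond <- function(x) mat[, paste0(x, c("_1", "_2")), drop = FALSE]
  lib <- if (is.null(lib_sizes)) {
    ## median-of-ratios condition depths: robust to genuinely
    ## differentially expressed genes, unlike raw totals
    cs <- vapply(c("P", "B", "HF", "HS"), function(x) rowSums(cond(x)),
                 numeric(nrow(mat)))
    pos <- rowSums(cs > 0) == ncol(cs)
    if (sum(pos) >= 10) {
      geo <- exp(rowMeans(log(cs[pos, , drop = FALSE])))
      apply(cs[pos, , drop = FALSE] / geo, 2, median)
    } else {
      colSums(cs)
    }
  } else {
    if (!all(c("P", "B", "HF", "HS") %in% names(lib_sizes)))
      stop("lib_sizes must be named P, B, HF, HS")
    lib_sizes[c("P", "B", "HF", "HS")]
  }
  testable <- apply(mat, 1, max) >= min_reads
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(mat[testable, , drop = FALSE])

  out <- gene_counts[c("gene_id",
                       intersect(c("chrom", "start", "end"),
                                 names(gene_counts)))]
  for (pair in names(.DE_PAIRS)) {
    a <- .DE_PAIRS[[pair]][1]; b <- .DE_PAIRS[[pair]][2]
    qcol <- paste0("q_", pair)
    if (!is.null(precomputed) && qcol %in% names(precomputed)) {
      out[[qcol]] <- precomputed[[qcol]][
        match(out$gene_id, precomputed$gene_id)]
      next
    }
    ca <- cond(a); cb <- cond(b)
    p <- rep(NA_real_, nrow(mat))
    p[testable] <- vapply(which(testable), function(i)
      de_pvalue(ca[i, ], cb[i, ], dispersion, lib[a], lib[b]),
      numeric(1))
    out[[qcol]] <- NA_real_
    out[[qcol]][testable] <- bh_fdr(p[testable])
  }

  ## condition means on a common depth scale
  sc <- median(lib) / lib
  mean_of <- function(x) rowMeans(cond(x)) * sc[x]
  mP <- mean_of("P"); mB <- mean_of("B")
  mHF <- mean_of("HF"); mHS <- mean_of("HS")

  sig <- function(q) !is.na(q) & q < alpha
  out$status_fertile <- classify_misexpression(
    mHF, mP, mB, sig(out$q_HF_vs_P), sig(out$q_HF_vs_B))
  out$status_sterile <- classify_misexpression(
    mHS, mP, mB, sig(out$q_HS_vs_P), sig(out$q_HS_vs_B))
  out$both_sig_fertile <- sig(out$q_HF_vs_P) & sig(out$q_HF_vs_B)
  out$both_sig_sterile <- sig(out$q_HS_vs_P) & sig(out$q_HS_vs_B)

  mf <- out$status_fertile != "not_misregulated"
  ms <- out$status_sterile != "not_misregulated"
  out$unique_to <- ifelse(mf & ms, "both",
                          ifelse(mf, "fertile",
                                 ifelse(ms, "sterile", "none")))
  attr(out, "alpha") <- alpha
  attr(out, "dispersion") <- dispersion
  out
}

#' Partition misexpressed genes into unique and shared sets
#'
#' @param calls Output of [misexpression_calls()].
#' @return List of gene-id vectors `fertile_unique`, `sterile_unique`,
#'   `shared`, `none`, plus a `counts` vector.
#' @export
unique_sets <- function(calls) {
  sets <- list(
    fertile_unique = calls$gene_id[calls$unique_to == "fertile"],
    sterile_unique = calls$gene_id[calls$unique_to == "sterile"],
    shared = calls$gene_id[calls$unique_to == "both"],
    none = calls$gene_id[calls$unique_to == "none"])
  sets$counts <- lengths(sets)
  sets
}

#' Functional-label enrichment between unique misexpression sets
#'
#' For each label, compares the fraction of labelled genes among annotated
#' fertile-unique genes with the fraction among annotated sterile-unique
#' genes using the pooled two-proportion Z-test.  The denominators are the
#' genes of each unique set that carry any annotation, matching the
#' annotated-subset convention of domain-level enrichment summaries.
#'
#' @param unique_fertile,unique_sterile Character vectors of gene ids.
#' @param labels Data frame with columns `gene_id`, `label` (a gene may
#'   carry several labels).
#' @return Data frame: label, k/n per hybrid, percentages (1 decimal),
#'   `z`, `p`.  Empty when either annotated set is empty (with a warning).
#' @export
label_enrichment <- function(unique_fertile, unique_sterile, labels) {
  stopifnot(all(c("gene_id", "label") %in% names(labels)))
  annotated <- unique(labels$gene_id)
  nf <- sum(unique_fertile %in% annotated)
  ns <- sum(unique_sterile %in% annotated)
  if (nf == 0 || ns == 0) {
    warning("an annotated unique set is empty; no enrichment computed")
    return(data.frame(label = character(0), k_fertile = integer(0),
                      n_fertile = integer(0), k_sterile = integer(0),
                      n_sterile = integer(0), pct_fertile = numeric(0),
                      pct_sterile = numeric(0), z = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE))
  }
  res <- lapply(unique(labels$label), function(lb) {
    with_lb <- unique(labels$gene_id[labels$label == lb])
    kf <- sum(unique_fertile %in% with_lb)
    ks <- sum(unique_sterile %in% with_lb)
    tst <- two_prop_z(kf, nf, ks, ns)
    data.frame(label = lb, k_fertile = kf, n_fertile = nf,
               k_sterile = ks, n_sterile = ns,
               pct_fertile = pct1(kf, nf), pct_sterile = pct1(ks, ns),
               z = tst$statistic, p = tst$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-chromosome distribution of uniquely misexpressed genes
#'
#' @param calls Output of [misexpression_calls()] (must carry `chrom`;
#'   genes with missing chromosome are pooled as `"U"`).
#' @return Data frame per chromosome: total genes, unique-misexpressed
#'   counts for each hybrid, proportions (4 decimals) and the
#'   fertile-vs-sterile two-proportion Z-test.
#' @export
chromosome_table <- function(calls) {
  chrom <- calls$chrom
  chrom[is.na(chrom) | chrom == ""] <- "U"
  res <- lapply(sort(unique(chrom)), function(cc) {
    i <- chrom == cc
    n <- sum(i)
    ks <- sum(calls$unique_to[i] == "sterile")
    kf <- sum(calls$unique_to[i] == "fertile")
    tst <- two_prop_z(ks, n, kf, n)
    data.frame(chrom = cc, n_genes = n,
               sterile = ks, prop_sterile = round(ks / n, 4),
               fertile = kf, prop_fertile = round(kf / n, 4),
               z = tst$statistic, p = tst$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Mapping-bias check on higher-expression splits
#'
#' Exact binomial test of how many genes show higher expression in one
#' species vs the other against an even split; a large p-value argues
#' against reference-mapping bias.
#'
#' @param n_P,n_B Numbers of genes with higher expression in each species.
#' @param alternative Passed to [binom_exact()] (default two-sided).
#' @return A `ctrex_test` list.
#' @export
check_bias <- function(n_P, n_B, alternative = "two.sided") {
  binom_exact(n_P, n_P + n_B, 0.5, alternative = alternative)
}
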