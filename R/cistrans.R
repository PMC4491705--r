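## The three-test regulatory-divergence classifier.
##
## For autosomal genes, three exact tests per gene:
##   test1: parent P vs parent B reads          (exact binomial vs 0.5)
##   test2: P allele vs B allele in the hybrid  (exact binomial vs 0.5)
##   test3: parental ratio vs hybrid allelic ratio (Fisher 2x2)
## Each test's p-values are FDR-corrected across all genes separately; the
## per-gene significance triple plus the direction of imbalance determines
## the divergence category.
##
## X-linked genes are hemizygous in hybrid males, so cis and trans effects
## on the X cannot be separated by allelic imbalance; instead the two
## reciprocal hybrids (which differ in maternal X but share autosomes) are
## compared: test2 becomes fertile-vs-sterile hybrid totals and test3 the
## parental ratio vs the hybrid-with-P-mother / hybrid-with-B-mother ratio.

.AUTOSOMAL_CATEGORIES <- c("conserved", "cis_only", "trans_only",
                           "compensatory", "cis_plus_trans", "cis_x_trans",
                           "ambiguous")
.XLINKED_CATEGORIES <- c("conserved", "x_only", "trans_only_autosomal",
                         "x_and_autosomal", "compensatory", "ambiguous")

#' Per-gene regulatory-divergence test p-values
#'
#' Computes the three exact-test p-values for every gene in a prepared
#' allele-count table (see [prepare_allele_counts()]).  Autosomal genes use
#' the chosen hybrid's allele counts; X-linked genes use per-hybrid totals
#' (each hybrid expresses only its maternal X allele).
#'
#' @param counts Normalized, zero-adjusted gene-level allele counts.
#' @param hybrid Which hybrid supplies autosomal allele counts; the fertile
#'   hybrid is the default so that sterility-specific effects do not enter
#'   the divergence assay.
#' @param x_chroms Chromosome names treated as X-linked.
#' @return Data frame: `gene_id`, `x_linked`, `p1`, `p2`, `p3`,
#'   `dir_parental`, `dir_hybrid` (`"P"`/`"B"`/`"tie"`).
#' @export
regulatory_tests <- function(counts, hybrid = c("fertile", "sterile"),
                             x_chroms = "X") {
  hybrid <- match.arg(hybrid)
  need <- paste0("norm_", names(.CTREX_SLOTS))
  if (!all(need %in% names(counts)))
    stop("counts must be normalized and zero-adjusted; run ",
         "prepare_allele_counts()")
  x_linked <- counts$chrom %in% x_chroms
  hp <- if (hybrid == "fertile") counts$norm_hybF_P else counts$norm_hybS_P
  hb <- if (hybrid == "fertile") counts$norm_hybF_B else counts$norm_hybS_B
  pp <- counts$norm_parent_P
  pb <- counts$norm_parent_B

  ## X-linked totals: maternal allele only.  Zero-adjustment put a 1 in the
  ## (absent) paternal slot; strip flagged adjustments before summing.
  strip <- function(x, flag) x - as.integer(flag)
  zf <- counts[paste0("zadj_", names(.CTREX_SLOTS))]
  hf_tot <- pmax(1L, strip(counts$norm_hybF_P, zf$zadj_hybF_P) +
                   strip(counts$norm_hybF_B, zf$zadj_hybF_B))
  hs_tot <- pmax(1L, strip(counts$norm_hybS_P, zf$zadj_hybS_P) +
                   strip(counts$norm_hybS_B, zf$zadj_hybS_B))

  t2a <- ifelse(x_linked, hf_tot, hp)
  t2b <- ifelse(x_linked, hs_tot, hb)

  p1 <- .binom_p(pp, pp + pb)
  p2 <- .binom_p(t2a, t2a + t2b)
  p3 <- .fisher_p(pp, pb, t2a, t2b)

  dirof <- function(a, b) ifelse(a > b, "P", ifelse(a < b, "B", "tie"))
  data.frame(gene_id = counts$gene_id, x_linked = x_linked,
             p1 = p1, p2 = p2, p3 = p3,
             dir_parental = dirof(pp, pb),
             dir_hybrid = dirof(t2a, t2b),
             stringsAsFactors = FALSE)
}

#' Map a significance triple to a divergence category
#'
#' Pure classification rule.  Autosomal mapping:
#' (NS,NS,NS) conserved; (S,S,NS) cis_only; (S,NS,S) trans_only;
#' (NS,S,S) compensatory; (S,S,S) cis_plus_trans when the same lineage's
#' allele is favored in parents and hybrid, cis_x_trans when opposite;
#' remaining patterns ambiguous.  X-linked mapping replaces cis_only with
#' x_only, trans_only with trans_only_autosomal, and (S,S,S) with
#' x_and_autosomal (no direction split).
#'
#' @param sig1,sig2,sig3 Logical vectors: is each test significant?
#' @param dir_parental,dir_hybrid `"P"`/`"B"`/`"tie"` direction of the
#'   parental and hybrid imbalance (used only for the (S,S,S) autosomal
#'   split).
#' @param x_linked Logical vector selecting the X-linked rule.
#' @return Character vector of categories.
#' @export
classify_pattern <- function(sig1, sig2, sig3,
                             dir_parental = "tie", dir_hybrid = "tie",
                             x_linked = FALSE) {
  n <- length(sig1)
  dir_parental <- rep_len(dir_parental, n)
  dir_hybrid <- rep_len(dir_hybrid, n)
  x_linked <- rep_len(x_linked, n)
  out <- character(n)
  pat <- paste0(ifelse(sig1, "S", "N"), ifelse(sig2, "S", "N"),
                ifelse(sig3, "S", "N"))
  base <- c(NNN = "conserved", SSN = NA, SNS = NA, NSS = "compensatory",
            SSS = NA, NNS = "ambiguous", NSN = "ambiguous",
            SNN = "ambiguous")
  out <- unname(base[pat])
  out[pat == "SSN"] <- ifelse(x_linked[pat == "SSN"], "x_only", "cis_only")
  out[pat == "SNS"] <- ifelse(x_linked[pat == "SNS"],
                              "trans_only_autosomal", "trans_only")
  sss <- pat == "SSS"
  if (any(sss)) {
    tie <- sss & (dir_parental == "tie" | dir_hybrid == "tie")
    if (any(tie))
      stop("internal inconsistency: significant tests with tied counts")
    out[sss] <- ifelse(x_linked[sss], "x_and_autosomal",
                       ifelse(dir_parental[sss] == dir_hybrid[sss],
                              "cis_plus_trans", "cis_x_trans"))
  }
  out
}

#' Classify regulatory divergence for all genes
#'
#' Runs [regulatory_tests()], converts each test's p-values to q-values
#' with [bh_fdr()] (one FDR family per test, across all genes of the same
#' compartment), applies the strict `q < q_threshold` significance rule and
#' maps the resulting pattern to a category with [classify_pattern()].
#'
#' @inheritParams regulatory_tests
#' @param q_threshold Significance threshold on the q-value (default 0.005,
#'   strict inequality).
#' @return Data frame with p/q values, the significance triple, directions
#'   and `category`.
#' @export
classify_regulation <- function(counts, hybrid = c("fertile", "sterile"),
                                q_threshold = 0.005, x_chroms = "X") {
  hybrid <- match.arg(hybrid)
  tests <- regulatory_tests(counts, hybrid = hybrid, x_chroms = x_chroms)
  for (comp in unique(tests$x_linked)) {
    i <- tests$x_linked == comp
    tests[i, c("q1", "q2", "q3")] <-
      lapply(tests[i, c("p1", "p2", "p3")], bh_fdr)
  }
  s1 <- tests$q1 < q_threshold
  s2 <- tests$q2 < q_threshold
  s3 <- tests$q3 < q_threshold
  tests$sig1 <- s1; tests$sig2 <- s2; tests$sig3 <- s3
  tests$category <- classify_pattern(s1, s2, s3, tests$dir_parental,
                                     tests$dir_hybrid, tests$x_linked)
  attr(tests, "hybrid") <- hybrid
  attr(tests, "q_threshold") <- q_threshold
  tests
}

#' Summarize regulatory-divergence calls
#'
#' Category counts and fractions plus an exact binomial test of cis- vs
#' trans-acting divergence.  The default counting rule scores `cis_only`
#' as one cis event, `trans_only` as one trans event, and each of
#' `cis_plus_trans`, `cis_x_trans` and `compensatory` as one of each (both
#' kinds of divergence are present); the rule is echoed in the output.
#'
#' @param calls Output of [classify_regulation()].
#' @return List with `counts`, `fractions`, `cis_n`, `trans_n`,
#'   `cis_fraction`, `cis_vs_trans` (a `ctrex_test` or NULL when no
#'   informative genes exist) and `counting_rule`.
#' @export
summarize_regulation <- function(calls) {
  stopifnot(nrow(calls) >= 1)
  cats <- if (any(calls$x_linked)) {
    c(.AUTOSOMAL_CATEGORIES, setdiff(.XLINKED_CATEGORIES,
                                     .AUTOSOMAL_CATEGORIES))
  } else .AUTOSOMAL_CATEGORIES
  counts <- table(factor(calls$category, levels = cats))
  auto <- calls[!calls$x_linked, , drop = FALSE]
  cis_n <- sum(auto$category %in%
                 c("cis_only", "cis_plus_trans", "cis_x_trans",
                   "compensatory"))
  trans_n <- sum(auto$category %in%
                   c("trans_only", "cis_plus_trans", "cis_x_trans",
                     "compensatory"))
  test <- if (cis_n + trans_n > 0)
    binom_exact(cis_n, cis_n + trans_n, 0.5) else NULL
  list(counts = counts,
       fractions = counts / nrow(calls),
       cis_n = cis_n, trans_n = trans_n,
       cis_fraction = if (cis_n + trans_n > 0)
         cis_n / (cis_n + trans_n) else NA_real_,
       cis_vs_trans = test,
       counting_rule = paste(
         "cis_only = 1 cis; trans_only = 1 trans; cis_plus_trans,",
         "cis_x_trans, compensatory = 1 cis + 1 trans"))
}
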