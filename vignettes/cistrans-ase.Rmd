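---
title: "Classifying cis/trans regulatory divergence and hybrid misexpression from allele-specific counts"
author: "ctrex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cis/trans regulatory divergence and hybrid misexpression from allele-specific counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrex)
```

## The problem

When two closely related species are crossed, both parental alleles of an
autosomal gene are transcribed in one F1 cell. Variants linked to the gene
itself (*cis*) shift the balance between the two alleles; diffusible
factors (*trans*) act on both alleles alike and therefore leave the
allelic balance untouched even when they drive a large expression
difference between the parental species. Comparing the parental expression
ratio with the hybrid allelic ratio therefore decomposes interspecies
regulatory divergence into *cis* and *trans* components.

`ctrex` implements this decomposition for a design with two parental
lines (denoted P and B), two reciprocal F1 male hybrids — one fertile
(P mother) and one sterile (B mother) — and two sequencing replicates per
sample. On top of the divergence classifier it provides the three
companion analyses such a study needs: classification of hybrid
misexpression into additive and transgressive forms, functional-label
enrichment in uniquely misexpressed gene sets, and a gene-by-gene
comparison of allelic ratios between the fertile and the sterile hybrid.
A synthetic-data generator with known truth makes every stage testable
end to end.

## The three-test classifier

For each autosomal gene with allele-resolved counts
(`parent_P`, `parent_B`, hybrid `P`-allele, hybrid `B`-allele), three
tests are run:

1. **Parental divergence** — exact binomial on
   `parent_P` out of `parent_P + parent_B` against 0.5.
2. **Hybrid allelic imbalance** — exact binomial on the hybrid's
   `P`-allele count against 0.5. The hybrid alleles share one cellular
   environment, so imbalance isolates *cis* divergence.
3. **Ratio difference** — Fisher's exact test on the 2×2 table of
   parental counts vs hybrid allele counts. Divergence in this ratio
   indicates a *trans* component.

Each test's p-values are converted to q-values by Benjamini–Hochberg
across all genes (one family per test, separately for the autosomal and
X-linked compartments), and significance is the strict rule
`q < 0.005`. The significance triple maps to a category:

| test 1 | test 2 | test 3 | category |
|---|---|---|---|
| NS | NS | NS | conserved |
| S  | S  | NS | cis_only |
| S  | NS | S  | trans_only |
| NS | S  | S  | compensatory |
| S  | S  | S  | cis_plus_trans / cis_x_trans |
| anything else | | | ambiguous |

The fully significant pattern is split by direction: when the same
lineage's allele is favored in the parents and in the hybrid the effects
reinforce (`cis_plus_trans`); opposite directions are antagonistic
(`cis_x_trans`). With discrete exact tests a significant result cannot
coexist with an exactly tied count, and the classifier enforces this with
an internal assertion.

Autosomal classification uses the fertile hybrid by default so that
sterility-specific expression changes cannot masquerade as divergence;
the sterile hybrid can be selected explicitly.

### X-linked genes

F1 males are hemizygous: each hybrid expresses only its maternal X
allele, so allelic imbalance cannot separate X-linked *cis* from
X-linked *trans*. Instead, the two reciprocal hybrids (which share a
hybrid autosomal background but differ in the maternal X) take the role
of the two alleles: test 2 compares the fertile and sterile hybrids'
totals, and test 3 compares the parental ratio with the
fertile-over-sterile ratio. The categories become `x_only` (any
X-linked regulation), `trans_only_autosomal`, `x_and_autosomal` and
`compensatory`.

## Misexpression in hybrids

A gene is *misregulated* in a hybrid when that hybrid differs
significantly (BH q < 0.05) from at least one parent. Misregulated
genes above both parental means are transgressive **over**, below both
**under**, and intermediate **additive**. Whether the gene was
significant against one or both parents is retained as a flag, since
either convention appears in practice. Genes misregulated in only one
hybrid form the fertile-unique and sterile-unique sets that carry the
biological signal of interest in an unidirectional-sterility design.

The built-in differential-expression test is a deliberately simple
stand-in, not a replica of a full count-model engine: replicate-summed
counts are compared by a conditional exact binomial with a library-size
offset, after deflating both sums by `1 + dispersion * mean`
(a quasi-likelihood-style correction; the genome-wide dispersion is
estimated by the method of moments from the replicate pairs).
Externally computed q-values can be supplied per comparison and are then
used verbatim.

Label enrichment between the unique sets uses the pooled two-proportion
Z-test on annotated genes only: the denominators are the members of each
unique set that carry at least one functional label, matching the
annotated-subset convention of domain-level summaries (e.g. 1 of 30
annotated fertile-unique vs 20 of 87 annotated sterile-unique genes
gives Z = 2.42, p = 0.016).

## Allelic-ratio comparison between hybrids

For every autosomal gene the table
`[fertile P, fertile B; sterile P, sterile B]` is tested with Fisher's
exact test, and log2 allelic ratios are computed from the normalized,
zero-adjusted counts (so they are always finite). The summary reports
the Pearson correlation of log2 ratios across genes, the fraction of
genes significant at q < 0.005 and q < 0.001, the top percentile by
fold change (`ceiling(0.01 N)` genes, ties broken by gene id), and the
ten largest *reversals* — genes whose allelic imbalance flips sign
between hybrids, ranked by `|log2 rF - log2 rS|`; the ranking statistic
is a design choice, as magnitude-of-reversal has no canonical
definition. Positional clusters of flagged genes are maximal runs of at
least `min_genes` genes with consecutive midpoint gaps at most
`window_bp` (defaults 3 and 150 kb, anchored loosely on the observed
scale of clustered reversals ~100 kb).

## Count preparation

- **Fixed SNPs**: a site is retained when each parent shows a single,
  different allele with ≥ 3 supporting reads.
- **Aggregation**: allele-resolved counts are summed over the fixed
  sites inside each gene span (1-based inclusive); hybrid reads are
  assigned to a parent of origin by allele identity. A SNP overlapping
  several genes counts toward each, with a warning. Genes with fewer
  than 20 combined parental reads are dropped — on the raw counts, so
  the support threshold does not drift with depth scaling.
- **Normalization**: counts are scaled per sample and rounded to
  integers (half away from zero) so the exact tests remain valid. The
  default size factor is the median-of-ratios estimator (median across
  genes of the sample count over the gene's geometric mean across
  samples). Raw per-sample totals are *not* used: when an appreciable
  fraction of genes is genuinely divergent, total counts absorb the
  signal itself and bias every downstream test — in simulations with
  2-fold effects on two-thirds of genes, total-count scaling produced
  5–18% false substantive calls on conserved genes, while
  median-of-ratios kept them below 1%. The same estimator is used for
  the condition depths of the differential-expression stand-in.
- **Zero adjustment**: remaining zero slots become 1 (flagged), making
  ratios and exact tests well-defined.

## The synthetic-data generator

The generator draws gene positions on a four-chromosome stand-in
genome (X 20 Mb, chr2 30 Mb, chr3 20 Mb, chr4 25 Mb), assigns each gene
a regulatory mode, and samples counts from the model (B is the
reference lineage, `dc`/`dt` are the log2 cis and trans effects):

- parent P mean: `lambda * 2^(dc + dt)`; parent B mean: `lambda`
- hybrid allele means: `0.5 * lambda * 2^dc` (P allele) and
  `0.5 * lambda` (B allele) — the alleles share one trans environment,
  so the allelic ratio isolates `2^dc` while the parental ratio
  compounds `2^(dc + dt)`
- X-linked genes express only the maternal allele; the hybrids sit at
  the autosomal-trans mid-level `2^(dt/2)` with the X-linked effect
  `2^dc` carried by the maternal allele

Modes fix the effect structure: `conserved` (`dc = dt = 0`),
`cis_only`, `trans_only`, `cis_plus_trans` (same sign),
`cis_x_trans` (opposite signs with `|dt| = 2|dc|`, so parental
divergence stays non-zero), and `compensatory` (`dt = -dc`, parents
equal, hybrid imbalanced). Default mode proportions (40% conserved,
21% cis-only, 17% cis+trans, 9% trans-only, 8% cis×trans, 5%
compensatory) describe a young species pair whose divergence is
dominated by cis-acting changes. Each diverged gene favors either
lineage with equal probability (`effect_signs = "balanced"`), matching
the directional balance seen in real interspecies comparisons; this
symmetry is also what keeps data-driven depth normalization
identifiable. `effect_signs = "positive"` fixes the direction for
worked examples.

Counts are Poisson, or negative binomial with variance
`mu + phi * mu^2` when `overdispersion = phi > 0` (default 0.05).
`mean_snp_reads` (default 200) is the expected SNP-supported depth per
gene per replicate; the two replicates of each sample are summed for
the allele-specific stages, so a sample carries twice that on average.
SNP-supported depth is deliberately decoupled from the log-normal
baseline expression `lambda` (which drives only the replicate-level
gene-total table): this makes the configured depth an exact,
interpretable design condition. Real data adds per-gene ASE-depth
variation (SNP density, gene length), mapping bias, indels and
multi-allelic sites — none of which are emulated, so passing tests
certify the statistical machinery under the stated conditions, not
robustness to those artifacts.

Per-gene counts are split multinomially over `1 + Poisson(2)` fixed
SNP sites to produce a realistic site-level table that aggregates back
exactly.

Misexpression truth is injected by multiplying a chosen hybrid's means
by `2^(±misexpr_fold_log2)` on both alleles (transgressive over/under;
the allelic ratio is untouched) or by moving the hybrid total to the
parental geometric mid (additive; only possible for genes with
parental divergence). Functional labels are assigned at a background
rate per label, multiplied by an enrichment factor among sterile-only
misexpressed genes. A separate knob (`ratio_shift_fraction`) applies a
sterile-hybrid-specific cis perturbation for testing the ratio
comparison. One interaction is worth noting: when parents diverge
strongly, both hybrids sit legitimately between them and are detected
as *additive* — this is correct behavior of the quadrant logic, so
recovery of injected sterile-only transgressive truth is assessed on a
conserved background.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `q_cistrans` | 0.005 | strict FDR threshold for the three divergence tests |
| `q_strict` | 0.001 | stricter reporting threshold for ratio differences |
| `alpha_de` | 0.05 | FDR threshold for differential expression |
| `min_reads` (fixed SNP) | 3 | per-parent supporting reads at a site |
| `min_gene_reads` | 20 | combined raw parental reads per retained gene |
| `min_reads` (DE) | 10 | max sample count needed for a gene to be testable |
| `cis_effect_log2`, `trans_effect_log2` | 1 | simulated effect sizes (2-fold) |
| `mean_snp_reads` | 200 | expected SNP reads per gene per replicate |
| `overdispersion` | 0.05 | NB dispersion phi; 0 = Poisson |
| `misexpr_fold_log2` | 2 | transgressive shift (4-fold) |
| `window_bp`, `min_genes` | 150000, 3 | cluster detection |

## Numerical choices

- Two-sided exact p-values use the minimum-likelihood rule with a
  `1 + 1e-7` relative tolerance on the point-probability comparison
  (the convention of mainstream exact-test implementations). The 2×2
  test is a direct hypergeometric sum, exercised against independent
  enumeration for every table with total ≤ 40.
- The pooled two-proportion Z-test uses no continuity correction; a
  degenerate pooled proportion yields Z = 0, p = 1 with a warning flag.
- Degenerate Fisher margins yield p = 1 with a warning flag.
- Normalized counts are rounded half away from zero; zero slots are
  adjusted to one after normalization and flagged.
- All significance rules are strict inequalities.
- Reproducibility: generation is fully determined by `seed`; pipeline
  outputs are byte-stable apart from tool-stamped date comments in
  GTF/BED headers.

## Problem sizes used by the test-suite and acceptance runs

Mode-recovery and FDR-control runs use 2,000 genes; misexpression
recovery 1,500; enrichment 4,000; the end-to-end determinism check 250.
These sizes give stable rates (binomial SE below ~1 percentage point on
the recovery estimates) while keeping a full run in tens of seconds.

## Known limitations

- Exact binomial and Fisher tests assume (conditionally) Poisson
  counts. Under overdispersion the between-sample tests (parental
  divergence, ratio difference) become anti-conservative, so some
  conserved genes are miscalled — most often as `trans_only`, whose
  signature is exactly "parents differ, hybrid balanced". The
  within-sample allelic-imbalance test is a binomial split of one
  total and is unaffected. This mirrors the behavior of the
  count-exact-test design itself; with the default `overdispersion =
  0.05` expect visibly imperfect conserved/trans separation, and set
  it to 0 to study the machinery under its nominal assumptions.
- The divergence classifier is categorical; it does not estimate the
  quantitative fraction of divergence attributable to cis
  (regression-style decomposition is out of scope).
- The DE stand-in is not a negative-binomial GLM; for real data,
  externally computed significance calls should be supplied.
- Parent-of-origin (imprinting) effects, mapping-bias correction and
  read-level simulation are not modeled.
- X-linked inference pools cis and trans on the X by construction of
  the hemizygous design; no method can separate them from these data.
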