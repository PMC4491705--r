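gc_row <- function(P, B, HF, HS, gene_id = "g1", chrom = "2") {
  data.frame(gene_id = gene_id, chrom = chrom,
             P_1 = P[1], P_2 = P[2], B_1 = B[1], B_2 = B[2],
             HF_1 = HF[1], HF_2 = HF[2], HS_1 = HS[1], HS_2 = HS[2],
             stringsAsFactors = FALSE)
}

test_that("the DE stand-in test reduces to an exact binomial", {
  expect_equal(de_pvalue(c(50, 50), c(50, 50)), 1.0)
  expect_equal(de_pvalue(c(0, 0), c(0, 0)), 1.0)
  expect_equal(de_pvalue(c(30, 30), c(10, 10)),
               binom_exact(60, 80)$p.value)
  expect_equal(de_pvalue(c(30, 30), c(10, 10)), 8.58e-6,
               tolerance = 1e-3)
  # overdispersion deflates the evidence
  expect_gt(de_pvalue(c(30, 30), c(10, 10), dispersion = 0.05),
            de_pvalue(c(30, 30), c(10, 10), dispersion = 0))
  # library-size offset shifts the null proportion
  expect_equal(de_pvalue(c(20, 20), c(10, 10), lib_a = 2, lib_b = 1), 1.0)
})

test_that("dispersion estimation recovers the simulated magnitude", {
  set.seed(19)
  mu <- rep(200, 4000)
  phi <- 0.1
  mat <- cbind(a1 = rnbinom(4000, mu = mu, size = 1 / phi),
               a2 = rnbinom(4000, mu = mu, size = 1 / phi))
  expect_equal(estimate_dispersion(mat), phi, tolerance = 0.3)
  pois <- cbind(rpois(4000, 100), rpois(4000, 100))
  expect_lt(estimate_dispersion(pois), 0.02)
})

test_that("misexpression status follows the quadrant logic", {
  # no significant comparison: not misregulated regardless of means
  expect_equal(classify_misexpression(10, 10, 10, FALSE, FALSE),
               "not_misregulated")
  # significantly above both parents: transgressive over
  expect_equal(classify_misexpression(40, 10, 12, TRUE, TRUE), "over")
  # below both parents: transgressive under
  expect_equal(classify_misexpression(3, 10, 12, TRUE, TRUE), "under")
  # intermediate with one significant call: additive
  expect_equal(classify_misexpression(20, 10, 30, TRUE, FALSE),
               "additive")
  # equality edge flagged
  expect_warning(
    st <- classify_misexpression(10, 10, 30, FALSE, TRUE), "additive")
  expect_equal(st, "additive")
  # parental-label swap with flipped significance is invariant
  expect_equal(classify_misexpression(40, 12, 10, TRUE, TRUE),
               classify_misexpression(40, 10, 12, TRUE, TRUE))
})

test_that("full misexpression calling on constructed tables", {
  tbl <- rbind(
    gc_row(c(100, 100), c(100, 100), c(100, 100), c(400, 400), "over_s"),
    gc_row(c(100, 100), c(100, 100), c(100, 100), c(25, 25), "under_s"),
    gc_row(c(100, 100), c(100, 100), c(400, 400), c(100, 100), "over_f"),
    gc_row(c(100, 100), c(100, 100), c(400, 400), c(400, 400), "shared"),
    gc_row(c(100, 100), c(100, 100), c(100, 100), c(100, 100), "flat"),
    gc_row(c(400, 400), c(100, 100), c(200, 200), c(200, 200), "addit"))
  eq <- c(P = 1, B = 1, HF = 1, HS = 1)
  calls <- misexpression_calls(tbl, alpha = 0.05, dispersion = 0,
                               lib_sizes = eq)
  got <- setNames(calls$status_sterile, calls$gene_id)
  expect_equal(unname(got[c("over_s", "under_s", "flat")]),
               c("over", "under", "not_misregulated"))
  expect_equal(unname(got["addit"]), "additive")
  ut <- setNames(calls$unique_to, calls$gene_id)
  expect_equal(unname(ut[c("over_s", "over_f", "shared", "flat")]),
               c("sterile", "fertile", "both", "none"))
  sets <- unique_sets(calls)
  expect_true("over_s" %in% sets$sterile_unique)
  expect_true("over_f" %in% sets$fertile_unique)
  expect_true("shared" %in% sets$shared)
  # untestable genes (below the read floor) stay untested
  low <- gc_row(c(3, 2), c(1, 1), c(2, 1), c(9, 8), "low")
  calls2 <- misexpression_calls(rbind(tbl, low), dispersion = 0,
                                lib_sizes = eq)
  expect_true(is.na(calls2$q_P_vs_B[calls2$gene_id == "low"]))
  expect_equal(calls2$status_sterile[calls2$gene_id == "low"],
               "not_misregulated")
})

test_that("sterile-only transgressive genes are recovered on simulation", {
  cfg <- sim_config(n_genes = 1000, seed = 17,
                    misexpr_fraction_sterile = 0.05,
                    misexpr_fraction_fertile = 0,
                    misexpr_fold_log2 = 2, overdispersion = 0,
                    misexpr_status_probs = c(over = 0.5, under = 0.5,
                                             additive = 0))
  sim <- simulate_ase(cfg)
  calls <- misexpression_calls(sim$gene_counts, alpha = 0.05)
  m <- merge(merge(calls, sim$truth, by = "gene_id"),
             sim$gene_counts[c("gene_id", "P_1", "P_2", "B_1", "B_2")],
             by = "gene_id")
  reps <- rowMeans(m[c("P_1", "P_2", "B_1", "B_2")])
  truthy <- m$misexpr_sterile %in% c("over", "under") & reps >= 100
  expect_gt(sum(truthy), 20)
  # the transgressive direction is recovered even when regulatory
  # divergence makes the fertile hybrid legitimately additive
  expect_gt(mean(m$status_sterile[truthy] ==
                   m$misexpr_sterile[truthy]), 0.8)
  # over + under + additive = misregulated
  mis <- m$status_sterile != "not_misregulated"
  expect_equal(sum(m$status_sterile %in% c("over", "under", "additive")),
               sum(mis))
  # hybrids of strongly diverged parents sit between them: additive
  # calls concentrate on diverged genes
  div <- abs(m$delta_cis + m$delta_trans) >= 1
  addf <- m$status_fertile == "additive"
  expect_gt(mean(div[addf]), 0.9)
})

test_that("label enrichment reproduces the annotated-subset Z-test", {
  labels <- data.frame(
    gene_id = c(paste0("f", 1:30), paste0("s", 1:87)),
    label = "anything", stringsAsFactors = FALSE)
  labels$label <- "background"
  pept <- data.frame(gene_id = c("f1", paste0("s", 1:20)),
                     label = "peptidase", stringsAsFactors = FALSE)
  labels <- rbind(labels, pept)
  enr <- label_enrichment(paste0("f", 1:30), paste0("s", 1:87), labels)
  row <- enr[enr$label == "peptidase", ]
  expect_equal(row$k_fertile, 1); expect_equal(row$n_fertile, 30)
  expect_equal(row$k_sterile, 20); expect_equal(row$n_sterile, 87)
  expect_equal(row$pct_fertile, 3.3)
  expect_equal(row$pct_sterile, 23.0)
  expect_lt(abs(row$z - 2.42), 0.005)
  expect_lt(abs(row$p - 0.016), 0.0005)
  # identical fractions: no signal
  same <- data.frame(gene_id = c(paste0("f", 1:17), paste0("s", 1:17)),
                     label = "x", stringsAsFactors = FALSE)
  same$label[c(1, 2, 18, 19)] <- "y"
  enr2 <- label_enrichment(paste0("f", 1:17), paste0("s", 1:17), same)
  expect_equal(enr2$z[enr2$label == "y"], 0)
  expect_equal(enr2$p[enr2$label == "y"], 1.0)
  # empty unique set: warning, empty result
  expect_warning(e3 <- label_enrichment(character(0), "s1", same),
                 "empty")
  expect_equal(nrow(e3), 0)
})

test_that("an enriched label stands out on simulated fixtures", {
  cfg <- sim_config(n_genes = 4000, seed = 18, overdispersion = 0,
                    mode_proportions = c(conserved = 1),
                    misexpr_fraction_sterile = 0.05,
                    misexpr_fraction_fertile = 0.05)
  sim <- simulate_ase(cfg)
  calls <- misexpression_calls(sim$gene_counts)
  sets <- unique_sets(calls)
  enr <- label_enrichment(sets$fertile_unique, sets$sterile_unique,
                          sim$labels)
  pept <- enr[enr$label == "peptidase", ]
  expect_gt(pept$z, 0)
  expect_gt(pept$pct_sterile, pept$pct_fertile)
  expect_lt(pept$p, median(enr$p[enr$label != "peptidase"]) + 1e-9)
})

test_that("chromosome table reports proportions at 4 decimals", {
  calls <- data.frame(
    gene_id = sprintf("g%04d", 1:4252), chrom = "X",
    unique_to = c(rep("sterile", 41), rep("fertile", 11),
                  rep("none", 4200)),
    stringsAsFactors = FALSE)
  tab <- chromosome_table(calls)
  expect_equal(tab$prop_sterile, 0.0096)
  expect_equal(tab$sterile, 41)
  # no misexpression: zero proportions, degenerate test
  calls$unique_to <- "none"
  tab0 <- chromosome_table(calls)
  expect_equal(tab0$prop_sterile, 0)
  expect_equal(tab0$z, 0)
  # equal counts in both hybrids: Z = 0
  calls$unique_to <- c(rep("sterile", 10), rep("fertile", 10),
                       rep("none", 4232))
  expect_equal(chromosome_table(calls)$z, 0)
})

test_that("mapping-bias check is an exact binomial on the split", {
  expect_equal(check_bias(50, 50)$p.value, 1.0)
  expect_equal(check_bias(7, 1)$p.value, 18 / 256)
  expect_equal(check_bias(0, 10)$p.value, 2 / 1024)
  # one-sided option available
  expect_equal(check_bias(0, 10, alternative = "less")$p.value, 1 / 1024)
})
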