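prep_from_slots <- function(pP, pB, hFP, hFB, hSP = hFP, hSB = hFB,
                            chrom = "2") {
  n <- length(pP)
  counts <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom,
    start = seq_len(n) * 10000L, end = seq_len(n) * 10000L + 1000L,
    n_snps = 1L,
    parent_P = as.integer(pP), parent_B = as.integer(pB),
    hybF_P = as.integer(hFP), hybF_B = as.integer(hFB),
    hybS_P = as.integer(hSP), hybS_B = as.integer(hSB),
    stringsAsFactors = FALSE)
  eq <- c(parent_P = 1, parent_B = 1, hybrid_fertile = 1,
          hybrid_sterile = 1)
  zero_adjust(normalize_counts(counts, library_sizes = eq))
}

test_that("per-gene three-test p-values match the exact-test oracles", {
  prep <- prep_from_slots(c(50, 7, 40), c(50, 1, 10),
                          c(50, 7, 25), c(50, 1, 25))
  tst <- regulatory_tests(prep)
  # perfect balance
  expect_equal(tst$p1[1], 1.0)
  expect_equal(tst$p2[1], 1.0)
  expect_equal(tst$p3[1], 1.0)
  # (7,1,7,1): binomial 18/256 twice, Fisher at its own modal table
  expect_equal(tst$p1[2], 18 / 256)
  expect_equal(tst$p2[2], 18 / 256)
  expect_equal(tst$p3[2], 1.0)
  # (40,10,25,25): strong parental skew, balanced hybrid
  expect_lt(tst$p1[3], 0.001)
  expect_equal(tst$p2[3], 1.0)
  expect_equal(tst$p3[3], oracle_fisher_p(40, 10, 25, 25))
  expect_equal(tst$p3[3], 0.003052, tolerance = 1e-4)
  expect_equal(tst$dir_parental[3], "P")
})

test_that("pattern classification is total and matches the truth tables", {
  sig <- c(FALSE, TRUE)
  grid <- expand.grid(s1 = sig, s2 = sig, s3 = sig)
  # autosomal mapping, direction 'same'
  got <- classify_pattern(grid$s1, grid$s2, grid$s3, "P", "P", FALSE)
  key <- paste0(ifelse(grid$s1, "S", "N"), ifelse(grid$s2, "S", "N"),
                ifelse(grid$s3, "S", "N"))
  want <- c(NNN = "conserved", SNN = "ambiguous", NSN = "ambiguous",
            SSN = "cis_only", NNS = "ambiguous", SNS = "trans_only",
            NSS = "compensatory", SSS = "cis_plus_trans")
  expect_equal(got, unname(want[key]))
  # opposite directions flip only the (S,S,S) cell
  got_op <- classify_pattern(grid$s1, grid$s2, grid$s3, "P", "B", FALSE)
  expect_equal(got_op[key == "SSS"], "cis_x_trans")
  expect_equal(got_op[key != "SSS"], got[key != "SSS"])
  # X-linked mapping
  got_x <- classify_pattern(grid$s1, grid$s2, grid$s3, "P", "P", TRUE)
  want_x <- c(NNN = "conserved", SNN = "ambiguous", NSN = "ambiguous",
              SSN = "x_only", NNS = "ambiguous",
              SNS = "trans_only_autosomal", NSS = "compensatory",
              SSS = "x_and_autosomal")
  expect_equal(got_x, unname(want_x[key]))
  # a tie with a fully significant pattern is impossible for exact tests
  expect_error(classify_pattern(TRUE, TRUE, TRUE, "tie", "P"),
               "inconsistency")
})

test_that("X-linked genes are classified from hybrid totals", {
  # x_only: parents 2-fold apart, hybrids mirror their mothers
  # trans_only_autosomal: parents apart, hybrids equal at the mid
  # conserved: everything level
  prep <- prep_from_slots(
    pP = c(400, 400, 200), pB = c(200, 200, 200),
    hFP = c(400, 283, 200), hFB = c(0, 0, 0),
    hSP = c(0, 0, 0), hSB = c(200, 283, 200),
    chrom = "X")
  calls <- classify_regulation(prep, q_threshold = 0.05)
  expect_true(all(calls$x_linked))
  expect_equal(calls$category, c("x_only", "trans_only_autosomal",
                                 "conserved"))
})

test_that("classifier recovers strong architectures on simulated data", {
  cfg <- small_auto_config(
    600, seed = 15,
    mode_proportions = c(conserved = 0.4, cis_only = 0.3,
                         trans_only = 0.3))
  sim <- simulate_ase(cfg)
  prep <- suppressWarnings(prepare_allele_counts(sim$snps, models_of(sim)))
  calls <- classify_regulation(prep, q_threshold = 0.005)
  m <- merge(calls, sim$truth[c("gene_id", "true_mode")], by = "gene_id")
  for (md in c("cis_only", "trans_only"))
    expect_gt(mean(m$category[m$true_mode == md] == md), 0.9)
})

test_that("swapping the P and B labels preserves categories", {
  cfg <- small_auto_config(400, seed = 16)
  sim <- simulate_ase(cfg)
  prep <- suppressWarnings(prepare_allele_counts(sim$snps, models_of(sim)))
  swapped <- prep
  for (pair in list(c("parent_P", "parent_B"), c("hybF_P", "hybF_B"),
                    c("hybS_P", "hybS_B"))) {
    for (pfx in c("", "norm_", "zadj_")) {
      a <- paste0(pfx, pair[1]); b <- paste0(pfx, pair[2])
      tmp <- swapped[[a]]; swapped[[a]] <- swapped[[b]]
      swapped[[b]] <- tmp
    }
  }
  c1 <- classify_regulation(prep)
  c2 <- classify_regulation(swapped)
  expect_equal(c1$category, c2$category)
  flip <- c(P = "B", B = "P", tie = "tie")
  expect_equal(unname(flip[c1$dir_parental]), c2$dir_parental)
})

test_that("summary counts cis and trans events and tests the balance", {
  calls <- data.frame(
    gene_id = sprintf("g%02d", 1:20), x_linked = FALSE,
    category = c(rep("cis_only", 15), rep("trans_only", 5)),
    stringsAsFactors = FALSE)
  s <- summarize_regulation(calls)
  expect_equal(s$cis_n, 15)
  expect_equal(s$trans_n, 5)
  expect_equal(s$cis_vs_trans$p.value, 0.04139, tolerance = 1e-4)
  # balanced case
  calls$category <- rep(c("cis_only", "trans_only"), 10)
  expect_equal(summarize_regulation(calls)$cis_vs_trans$p.value, 1.0)
  # all conserved: no informative genes, no test
  calls$category <- "conserved"
  s3 <- summarize_regulation(calls)
  expect_null(s3$cis_vs_trans)
  expect_equal(unname(s3$fractions["conserved"]), 1)
  # joint categories count toward both kinds
  calls$category <- c(rep("compensatory", 10), rep("cis_x_trans", 10))
  s4 <- summarize_regulation(calls)
  expect_equal(s4$cis_n, 20)
  expect_equal(s4$trans_n, 20)
})
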