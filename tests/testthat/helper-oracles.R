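# Independent oracles: brute-force enumeration built on combinatorial
# identities (choose), deliberately separate from the dbinom/dhyper code
# paths inside the package.

TOL <- 1 + 1e-7

# two-sided exact binomial by direct enumeration of all n+1 outcomes
oracle_binom_p <- function(k, n, p0 = 0.5) {
  pr <- choose(n, 0:n) * p0^(0:n) * (1 - p0)^(n - (0:n))
  min(1, sum(pr[pr <= pr[k + 1] * TOL]))
}

# two-sided Fisher by enumerating every table with the observed margins
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; m1 <- a + c; N <- r1 + r2
  lo <- max(0, m1 - r2); hi <- min(r1, m1)
  xs <- lo:hi
  pr <- choose(r1, xs) * choose(r2, m1 - xs) / choose(N, m1)
  min(1, sum(pr[pr <= pr[a - lo + 1] * TOL]))
}

# small autosomal-only configuration used by several simulation tests
small_auto_config <- function(n_genes, seed, ...) {
  sim_config(
    n_genes = n_genes,
    chromosomes = data.frame(name = c("2", "3", "4"),
                             length = c(30e6, 20e6, 25e6),
                             is_x = FALSE, stringsAsFactors = FALSE),
    misexpr_fraction_sterile = 0, misexpr_fraction_fertile = 0,
    overdispersion = 0, seed = seed, ...)
}

# gene models straight from a simulation truth table
models_of <- function(sim) sim$truth[c("gene_id", "chrom", "start", "end")]
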