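## Synthetic allele-specific expression data with known truth.
##
## Expression model (B is the reference lineage, c_B = t_B = 1):
##   parent P mean   = lambda * 2^(dc + dt)
##   parent B mean   = lambda
##   hybrid alleles share one cellular environment whose trans component is
##   the geometric mid of the parental trans factors, so
##   hybrid P-allele  = 1/2 * lambda * 2^(dc + dt/2)
##   hybrid B-allele  = 1/2 * lambda * 2^(dt/2)
## The hybrid allelic ratio therefore isolates the cis effect (2^dc) while
## the parental ratio compounds cis and trans (2^(dc+dt)).
##
## X-linked genes are hemizygous in males: each hybrid expresses only the
## maternal allele.  dc is reinterpreted as the combined X-linked effect and
## dt as the autosomal trans effect:
##   fertile hybrid (P mother) = lambda * 2^(dc + dt/2)
##   sterile hybrid (B mother) = lambda * 2^(dt/2)

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_ase()].  Defaults describe
#' a closely related species pair with two-fold regulatory effects, a
#' regulatory-mode composition loosely matching what is observed between
#' young Drosophila species (cis-dominated divergence), and a sterile hybrid
#' carrying extra transgressive misexpression.
#'
#' @param n_genes Number of genes.
#' @param chromosomes Data frame with columns `name`, `length` (bp) and
#'   `is_x`; genes are placed proportionally to length, without overlap.
#' @param mode_proportions Named fractions over the six regulatory modes
#'   (`conserved`, `cis_only`, `trans_only`, `cis_plus_trans`,
#'   `cis_x_trans`, `compensatory`); must sum to 1.
#' @param cis_effect_log2,trans_effect_log2 Effect magnitudes (log2 fold);
#'   each gene receives a random sign.  `cis_x_trans` genes use an opposing
#'   trans effect of twice the cis magnitude so parental divergence stays
#'   non-zero; `compensatory` genes use exactly opposite effects.
#' @param baseline_log_mean,baseline_log_sd Natural-log parameters of the
#'   log-normal per-gene baseline expression.
#' @param mean_snp_reads Average SNP-supported reads per gene per
#'   replicate; each sample carries two replicates, summed for the
#'   allele-specific stages.
#' @param effect_signs `"balanced"` (default): each diverged gene favors
#'   either lineage with equal probability, matching the directional
#'   balance seen in real interspecies comparisons.  `"positive"`: all
#'   effects favor the P lineage (useful for worked examples with a known
#'   direction).
#' @param overdispersion Negative-binomial dispersion phi
#'   (variance = mu + phi mu^2); 0 gives Poisson sampling.
#' @param depth_factors Named per-sample relative sequencing depths.
#' @param misexpr_fraction_sterile,misexpr_fraction_fertile Fractions of
#'   genes misexpressed only in the sterile / only in the fertile hybrid.
#' @param misexpr_fold_log2 Magnitude (log2) of transgressive misexpression.
#' @param misexpr_status_probs Probabilities of `over`, `under`, `additive`
#'   for a misexpressed gene (additive requires parental divergence and
#'   falls back to over/under without it).
#' @param ratio_shift_fraction Fraction of autosomal genes receiving a
#'   sterile-hybrid-specific cis perturbation of the allelic ratio.
#' @param ratio_shift_log2 Magnitude (log2) of that perturbation.
#' @param label_table Data frame with columns `label`, `background`
#'   (genome-wide labelling probability) and `enrichment` (multiplier among
#'   sterile-only misexpressed genes).
#' @param mean_snps_per_gene Average number of fixed SNP sites per gene
#'   (at least one site is always placed).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `ctrex_sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       chromosomes = data.frame(
                         name = c("X", "2", "3", "4"),
                         length = c(20e6, 30e6, 20e6, 25e6),
                         is_x = c(TRUE, FALSE, FALSE, FALSE),
                         stringsAsFactors = FALSE),
                       mode_proportions = c(conserved = 0.40,
                                            cis_only = 0.21,
                                            trans_only = 0.09,
                                            cis_plus_trans = 0.17,
                                            cis_x_trans = 0.08,
                                            compensatory = 0.05),
                       cis_effect_log2 = 1,
                       trans_effect_log2 = 1,
                       baseline_log_mean = 0,
                       baseline_log_sd = 0.5,
                       mean_snp_reads = 200,
                       effect_signs = c("balanced", "positive"),
                       overdispersion = 0.05,
                       depth_factors = c(parent_P = 1, parent_B = 1,
                                         hybrid_fertile = 1,
                                         hybrid_sterile = 1),
                       misexpr_fraction_sterile = 0.05,
                       misexpr_fraction_fertile = 0.02,
                       misexpr_fold_log2 = 2,
                       misexpr_status_probs = c(over = 0.4, under = 0.4,
                                                additive = 0.2),
                       ratio_shift_fraction = 0,
                       ratio_shift_log2 = 2,
                       label_table = data.frame(
                         label = c("peptidase", "oxidoreductase",
                                   "cell_adhesion"),
                         background = c(0.05, 0.05, 0.03),
                         enrichment = c(5, 1, 1),
                         stringsAsFactors = FALSE),
                       mean_snps_per_gene = 3,
                       seed = 1L) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length", "is_x") %in% names(chromosomes)),
            all(chromosomes$length > 0))
  if (!all(names(mode_proportions) %in% .CTREX_AUTOSOMAL_MODES))
    stop("unknown regulatory mode(s): ",
         paste(setdiff(names(mode_proportions), .CTREX_AUTOSOMAL_MODES),
               collapse = ", "))
  mp <- setNames(numeric(length(.CTREX_AUTOSOMAL_MODES)),
                 .CTREX_AUTOSOMAL_MODES)
  mp[names(mode_proportions)] <- mode_proportions
  mode_proportions <- mp
  if (abs(sum(mode_proportions) - 1) > 1e-9)
    stop("mode_proportions must sum to 1")
  if (any(mode_proportions < 0 | mode_proportions > 1))
    stop("mode_proportions must lie in [0, 1]")
  if (!setequal(names(depth_factors), .CTREX_SAMPLES) ||
      any(depth_factors <= 0))
    stop("depth_factors must be positive and named for all four samples")
  stopifnot(overdispersion >= 0, mean_snp_reads > 0,
            misexpr_fraction_sterile >= 0, misexpr_fraction_sterile <= 1,
            misexpr_fraction_fertile >= 0, misexpr_fraction_fertile <= 1,
            ratio_shift_fraction >= 0, ratio_shift_fraction <= 1,
            mean_snps_per_gene >= 1)
  effect_signs <- match.arg(effect_signs)
  cfg <- list(
    n_genes = as.integer(n_genes),
    chromosomes = chromosomes,
    effect_signs = effect_signs,
    mode_proportions = mode_proportions[.CTREX_AUTOSOMAL_MODES],
    cis_effect_log2 = cis_effect_log2,
    trans_effect_log2 = trans_effect_log2,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    mean_snp_reads = mean_snp_reads,
    overdispersion = overdispersion,
    depth_factors = depth_factors[.CTREX_SAMPLES],
    misexpr_fraction_sterile = misexpr_fraction_sterile,
    misexpr_fraction_fertile = misexpr_fraction_fertile,
    misexpr_fold_log2 = misexpr_fold_log2,
    misexpr_status_probs = misexpr_status_probs /
      sum(misexpr_status_probs),
    ratio_shift_fraction = ratio_shift_fraction,
    ratio_shift_log2 = ratio_shift_log2,
    label_table = label_table,
    mean_snps_per_gene = mean_snps_per_gene,
    seed = as.integer(seed)
  )
  class(cfg) <- "ctrex_sim_config"
  cfg
}

## count sampler: Poisson when phi == 0, NB with variance mu + phi mu^2
.draw_counts <- function(mu, phi) {
  as.integer(if (phi == 0) rpois(length(mu), mu) else
    rnbinom(length(mu), mu = mu, size = 1 / phi))
}

## exact-proportion mode assignment, shuffled
.assign_modes <- function(n, props) {
  base <- floor(props * n)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(props * n - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  sample(rep(names(props), base))
}

## expected classifier category for each true mode (X-linked genes collapse
## cis and trans on the X into a single compartment)
.expected_category <- function(mode, x_linked) {
  xmap <- c(conserved = "conserved", cis_only = "x_only",
            trans_only = "trans_only_autosomal",
            cis_plus_trans = "x_and_autosomal",
            cis_x_trans = "x_and_autosomal",
            compensatory = "compensatory")
  ifelse(x_linked, xmap[mode], mode)
}

#' Generate synthetic parental and reciprocal-hybrid count data
#'
#' Draws gene positions, regulatory modes and effect sizes, then samples
#' SNP-supported allele counts for the two parents and both hybrids, a
#' replicate-level gene-total expression table, a per-site SNP table and a
#' truth table.  The sterile hybrid descends from a B mother, the fertile
#' hybrid from a P mother, so X-linked genes express the P allele in the
#' fertile and the B allele in the sterile hybrid.
#'
#' @param config A [sim_config()] object.
#' @return A `ctrex_sim` list with elements `truth`, `counts` (gene-level
#'   allele counts), `gene_counts` (2 replicates x 4 conditions),
#'   `snps` (per-site allele counts), `labels` (gene/label pairs) and
#'   `config`.
#' @export
simulate_ase <- function(config) {
  if (!inherits(config, "ctrex_sim_config"))
    stop("'config' must be built by sim_config()")
  set.seed(config$seed)
  n <- config$n_genes
  ch <- config$chromosomes

  ## non-overlapping gene placement on a slot grid
  slot <- 6000L
  n_slots <- floor(ch$length / slot)
  if (n > sum(n_slots)) stop("too many genes for the chromosome set")
  all_slots <- unlist(lapply(seq_len(nrow(ch)), function(i)
    seq_len(n_slots[i]) + i * 1e6))     # encode chromosome in the slot id
  pick <- sort(sample(all_slots, n))
  chrom_idx <- as.integer(pick %/% 1e6)
  slot_idx <- as.integer(pick %% 1e6)
  glen <- sample(500:5000, n, replace = TRUE)
  start <- (slot_idx - 1L) * slot + sample(1:500, n, replace = TRUE)
  end <- start + glen - 1L
  x_linked <- ch$is_x[chrom_idx]
  gene_id <- sprintf("gene%05d", seq_len(n))

  ## regulatory modes and effect sizes; each diverged gene favors either
  ## lineage with equal probability (interspecies divergence is
  ## directionally balanced), so depth normalization stays identifiable
  mode <- .assign_modes(n, config$mode_proportions)
  sgn <- if (config$effect_signs == "positive") rep(1, n) else
    sample(c(-1, 1), n, replace = TRUE)
  dc <- numeric(n); dt <- numeric(n)
  has_cis <- mode %in% c("cis_only", "cis_plus_trans", "cis_x_trans",
                         "compensatory")
  dc[has_cis] <- (sgn * config$cis_effect_log2)[has_cis]
  dt[mode == "trans_only"] <-
    (sgn * config$trans_effect_log2)[mode == "trans_only"]
  i <- mode == "cis_plus_trans"
  dt[i] <- sign(dc[i]) * abs(config$trans_effect_log2)
  i <- mode == "cis_x_trans"
  dt[i] <- -2 * dc[i]
  i <- mode == "compensatory"
  dt[i] <- -dc[i]

  ## baseline expression and read-depth scale
  lambda <- rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)
  scale <- config$mean_snp_reads / mean(lambda)

  ## relative (lambda-free) condition means.  Hybrid alleles share one
  ## trans environment, taken as the reference (B) level, so only the cis
  ## effect appears in the hybrid; X-linked hybrids sit at the autosomal
  ## trans mid-level with the X effect carried by the maternal allele.
  rel_P <- 2^(dc + dt)
  rel_B <- rep(1, n)
  rel_hyb_P <- 0.5 * 2^dc              # per hybrid allele, autosomal
  rel_hyb_B <- rep(0.5, n)
  rel_HF <- ifelse(x_linked, 2^(dc + dt / 2), rel_hyb_P + rel_hyb_B)
  rel_HS <- ifelse(x_linked, 2^(dt / 2), rel_hyb_P + rel_hyb_B)

  ## sterile-hybrid-specific cis perturbation of the allelic ratio
  ratio_shift <- rep(0, n)
  auto <- which(!x_linked)
  n_shift <- round(config$ratio_shift_fraction * length(auto))
  if (n_shift > 0) {
    sel <- sample(auto, n_shift)
    ratio_shift[sel] <- sample(c(-1, 1), n_shift, replace = TRUE) *
      config$ratio_shift_log2
  }

  ## misexpression truth: disjoint sterile-only and fertile-only sets
  mis_f <- rep("none", n); mis_s <- rep("none", n)
  n_s <- round(config$misexpr_fraction_sterile * n)
  n_f <- round(config$misexpr_fraction_fertile * n)
  chosen <- sample(n, n_s + n_f)
  pick_status <- function(idx) {
    st <- sample(names(config$misexpr_status_probs), length(idx),
                 replace = TRUE, prob = config$misexpr_status_probs)
    no_div <- abs(dc[idx] + dt[idx]) < 0.5
    st[st == "additive" & no_div] <-
      sample(c("over", "under"), sum(st == "additive" & no_div),
             replace = TRUE)
    st
  }
  if (n_s > 0) mis_s[chosen[seq_len(n_s)]] <-
    pick_status(chosen[seq_len(n_s)])
  if (n_f > 0) mis_f[chosen[n_s + seq_len(n_f)]] <-
    pick_status(chosen[n_s + seq_len(n_f)])

  mis_factor <- function(status) {
    ifelse(status == "over", 2^config$misexpr_fold_log2,
           ifelse(status == "under", 2^(-config$misexpr_fold_log2), 1))
  }
  ## additive misexpression: move the hybrid total to the parental
  ## geometric mid (detectable only when the parents diverge)
  mid <- 2^((dc + dt) / 2)
  fac_HF <- ifelse(mis_f == "additive", mid / rel_HF, mis_factor(mis_f))
  fac_HS <- ifelse(mis_s == "additive", mid / rel_HS, mis_factor(mis_s))
  rel_HF <- rel_HF * fac_HF
  rel_HS <- rel_HS * fac_HS

  ## SNP-supported allele counts (one draw per sample = 2 replicates
  ## pooled).  SNP-supported depth is held at the configured per-gene mean
  ## so that statistical power is a direct function of the configuration;
  ## the log-normal baseline drives the gene-total expression table below.
  phi <- config$overdispersion
  dep <- config$depth_factors
  mu_snp <- rep(2 * config$mean_snp_reads, n)   # two replicates per sample
  parent_P <- .draw_counts(dep["parent_P"] * mu_snp * rel_P, phi)
  parent_B <- .draw_counts(dep["parent_B"] * mu_snp * rel_B, phi)
  totF <- .draw_counts(dep["hybrid_fertile"] * mu_snp * rel_HF, phi)
  totS <- .draw_counts(dep["hybrid_sterile"] * mu_snp * rel_HS, phi)
  frac_P <- 2^dc / (1 + 2^dc)                       # fertile hybrid
  frac_P_S <- 2^(dc + ratio_shift) / (1 + 2^(dc + ratio_shift))
  hybF_P <- ifelse(x_linked, totF, rbinom(n, totF, frac_P))
  hybF_B <- ifelse(x_linked, 0L, totF - hybF_P)
  hybS_B <- ifelse(x_linked, totS, totS - rbinom(n, totS, frac_P_S))
  hybS_P <- totS - hybS_B

  counts <- data.frame(
    gene_id = gene_id, chrom = ch$name[chrom_idx],
    start = start, end = end, x_linked = x_linked,
    parent_P = parent_P, parent_B = parent_B,
    hybF_P = as.integer(hybF_P), hybF_B = as.integer(hybF_B),
    hybS_P = as.integer(hybS_P), hybS_B = as.integer(hybS_B),
    stringsAsFactors = FALSE
  )

  ## replicate-level gene totals for the differential-expression stage
  ## (each replicate at the configured mean depth, modulated by the
  ## log-normal baseline)
  mu_expr <- scale * lambda
  rep_mu <- function(sample, rel) dep[sample] * mu_expr * rel
  gene_counts <- data.frame(
    gene_id = gene_id, chrom = ch$name[chrom_idx],
    start = start, end = end,
    P_1 = .draw_counts(rep_mu("parent_P", rel_P), phi),
    P_2 = .draw_counts(rep_mu("parent_P", rel_P), phi),
    B_1 = .draw_counts(rep_mu("parent_B", rel_B), phi),
    B_2 = .draw_counts(rep_mu("parent_B", rel_B), phi),
    HF_1 = .draw_counts(rep_mu("hybrid_fertile", rel_HF), phi),
    HF_2 = .draw_counts(rep_mu("hybrid_fertile", rel_HF), phi),
    HS_1 = .draw_counts(rep_mu("hybrid_sterile", rel_HS), phi),
    HS_2 = .draw_counts(rep_mu("hybrid_sterile", rel_HS), phi),
    stringsAsFactors = FALSE
  )

  ## functional labels with enrichment among sterile-only misexpressed genes
  lt <- config$label_table
  sterile_only <- mis_s != "none" & mis_f == "none"
  lab_list <- lapply(seq_len(nrow(lt)), function(i) {
    pr <- ifelse(sterile_only,
                 pmin(1, lt$background[i] * lt$enrichment[i]),
                 lt$background[i])
    hit <- runif(n) < pr
    if (!any(hit)) return(NULL)
    data.frame(gene_id = gene_id[hit], label = lt$label[i],
               stringsAsFactors = FALSE)
  })
  labels <- do.call(rbind, lab_list)
  if (is.null(labels))
    labels <- data.frame(gene_id = character(0), label = character(0),
                         stringsAsFactors = FALSE)
  labels <- labels[order(labels$gene_id, labels$label), , drop = FALSE]
  rownames(labels) <- NULL

  ## per-site SNP table: split each gene's counts over its fixed sites
  n_sites <- 1L + rpois(n, config$mean_snps_per_gene - 1)
  snps <- .split_sites(counts, n_sites)

  truth <- data.frame(
    gene_id = gene_id, chrom = ch$name[chrom_idx],
    start = start, end = end, x_linked = x_linked,
    true_mode = mode, delta_cis = dc, delta_trans = dt,
    category_truth = .expected_category(mode, x_linked),
    misexpr_fertile = mis_f, misexpr_sterile = mis_s,
    ratio_shift = ratio_shift,
    stringsAsFactors = FALSE
  )

  structure(list(truth = truth, counts = counts, gene_counts = gene_counts,
                 snps = snps, labels = labels, config = config),
            class = "ctrex_sim")
}

## distribute gene-level allele counts multinomially over SNP sites
.split_sites <- function(counts, n_sites) {
  nt <- c("A", "C", "G", "T")
  rows <- vector("list", nrow(counts))
  slots <- c("parent_P", "parent_B", "hybF_P", "hybF_B", "hybS_P", "hybS_B")
  for (g in seq_len(nrow(counts))) {
    k <- n_sites[g]
    span <- counts$end[g] - counts$start[g]
    pos <- counts$start[g] + sort(sample.int(span + 1L, k) - 1L)
    ref <- sample(nt, k, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), character(1))
    split1 <- function(total) {
      if (k == 1L) return(total)
      as.vector(stats::rmultinom(1, total, rep(1 / k, k)))
    }
    m <- vapply(slots, function(s) split1(counts[[s]][g]),
                numeric(n_sites[g]))
    if (k == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, slots))
    rows[[g]] <- data.frame(
      chrom = counts$chrom[g], pos = pos, ref_P = ref, alt_B = alt,
      parentP_P = as.integer(m[, "parent_P"]), parentP_B = 0L,
      parentB_P = 0L, parentB_B = as.integer(m[, "parent_B"]),
      hybF_P = as.integer(m[, "hybF_P"]),
      hybF_B = as.integer(m[, "hybF_B"]),
      hybS_P = as.integer(m[, "hybS_P"]),
      hybS_B = as.integer(m[, "hybS_B"]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
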