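Package: ctrex
Title: Cis/Trans Regulatory Divergence and Hybrid Misexpression from
    Allele-Specific Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the mode of interspecies regulatory divergence
    (cis, trans, compensatory, reinforcing or antagonistic combinations)
    from allele-specific read counts in F1 hybrids, with a dedicated
    scheme for hemizygous X-linked genes in males.  Classifies hybrid
    misexpression as additive or transgressive relative to the parental
    species, tests functional-label enrichment in uniquely misexpressed
    gene sets, and compares allelic expression ratios between a fertile
    and a sterile F1 hybrid, including reversal detection and positional
    clustering.  A synthetic-data generator produces parental and
    reciprocal-hybrid count tables with known regulatory modes so the
    whole pipeline is testable end to end without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
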