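Package: locusdiff
Title: Population Differentiation and Polygenic Risk at Candidate Disease Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic analysis of panels of candidate disease loci
    genotyped across structured populations. Reads VCF genotypes, a sample
    panel and a locus table into an effect-allele dosage matrix; computes
    per-population allele frequencies, a monomorphism census, exact
    Hardy-Weinberg tests and diversity summaries (observed and expected
    heterozygosity, Shannon's information index, fixation index);
    quantifies interpopulation differentiation by PhiPT from an analysis of
    molecular variance with permutation significance, Nei's standard genetic
    distance, exact G-tests of genic and genotypic differentiation, and
    principal coordinate analysis; scores per-population enrichment and
    depletion of effect alleles with a signed, capped, FDR-adjusted
    hypergeometric framework; and computes unweighted and weighted polygenic
    risk scores with nonparametric group comparison (Kruskal-Wallis, Dunn's
    post hoc test, Benjamini-Hochberg correction). Includes a
    Balding-Nichols simulator of multi-population genotype data with known
    divergence for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
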