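Package: grousepop
Title: Conservation Genetics of Captive and Reintroduced Grouse Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for genetic assessment of captive breeding
    flocks and reintroduced wild populations of grouse (birds with ZZ/ZW sex
    chromosomes), built around microsatellite and mitochondrial control-region
    data. Provides non-invasive (faecal) genotype consolidation with
    probability-of-identity screening, genotyping error-rate estimation,
    per-locus diversity statistics (allele counts, unbiased expected and
    observed heterozygosity, F_IS, exact Hardy-Weinberg tests with FDR
    correction, maximum-likelihood null-allele frequency), a sex-linkage
    screen that detects Z-linked microsatellite loci from sex-split
    heterozygosity patterns, Bayesian admixture-model clustering with
    replicate runs and Evanno Delta-K model choice, and mtDNA haplotype and
    nucleotide diversity summaries. A synthetic-data generator emulating a
    two-lineage, two-population faecal-sampling design makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    Biostrings,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
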