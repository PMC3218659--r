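Package: ldsplit
Title: Association of SNP Alleles with Recombination Hotspot Intensity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sequence polymorphisms associated with variation in the
    intensity of meiotic recombination hotspots.  A phased haplotype panel is
    split into two subpopulations by the alleles of a candidate SNP, a
    population recombination rate map (rho = 4*Ne*r per inter-SNP segment) is
    estimated for each subpopulation with a haplotype-copying composite
    likelihood, and the normalized difference of hotspot strengths is tested
    against a permutation null with MAF-matched standardization, Shapiro
    normality gating, Grubbs outlier-chromosome removal and Storey q-values.
    Includes a hotspot caller for piecewise-constant rate maps, a forward-time
    diploid simulator of crossover and biased gene conversion with a planted
    causal SNP, benchmark evaluation metrics, and genomic-feature enrichment
    tests for candidate versus control SNPs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    Biostrings
Config/testthat/edition: 3
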