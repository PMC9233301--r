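Package: hapsharing
Title: Haplotype-Sharing Analysis of Population Structure and Recent Demography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for haplotype-based analysis of fine-scale
    population structure and recent demographic history from phased diploid
    genotypes. Implements positional Burrows-Wheeler transform (PBWT) chunk
    painting into chunkcount and chunklength coancestry matrices, recursive
    Leiden community detection on the edge-filtered coancestry network,
    non-negative least-squares haplotype-sharing profiles, total variation
    distance and Hudson's Fst between clusters, identity-by-descent (IBD)
    segment detection with gap merging, recent effective population size
    estimation from the IBD segment-length spectrum with bootstrap intervals,
    runs-of-homozygosity scanning and the F_ROH and F_SNP inbreeding
    coefficients. A forward-in-time pedigree and recombination simulator with
    ground-truth IBD output provides a truth set for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
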