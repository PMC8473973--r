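Package: invscan
Title: Detection of Candidate Chromosomal Inversions from SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering candidate chromosomal inversions
    (and other large structural variants) from population-scale SNP
    genotype data. Implements local principal component analysis in
    non-overlapping SNP windows, classical multidimensional scaling of
    between-window covariance distances, Tukey-fence outlier scanning to
    call candidate regions, karyotype assignment by region PCA clustering
    with heterozygosity validation, EM-based estimation of gametic r2
    linkage disequilibrium from unphased genotypes (pooled, stratified by
    karyotype, and as a degree-filtered LD network), and a synthetic-data
    generator that plants inversions with known truth labels for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
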