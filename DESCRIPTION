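Package: glscan
Title: Genotype-Likelihood Population Genomics for Low-Coverage Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A likelihood-based population-genomics toolkit for low-coverage
    (~1x) whole-genome sequencing of diploids. Works from per-site,
    per-individual biallelic read counts or Beagle-format genotype likelihoods
    without ever calling genotypes: EM estimation of population allele
    frequencies, SNP calling and site filtering, sample-allele-frequency (SAF)
    likelihoods, folded site-frequency-spectrum estimation, windowed nucleotide
    diversity (pi, Watterson's theta, Tajima's D), 2D-SFS based FST
    (Hudson/Bhatia and Reynolds) and dxy, binary super-pool differentiation
    scans with empirical outlier thresholds, independent-signal merging,
    gene-proximity annotation from GFF3, VIF-based LD pruning, expected-dosage
    PCA, and windowed read-depth QC for collapsed duplicated regions. Includes
    a calibrated synthetic-data generator (Balding-Nichols population model,
    Poisson depth, three-way base-error model) so every stage is testable with
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
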