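Package: xselscan
Title: Selection-Signature Scans on the X Chromosome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Within-population selection-signature scanning for SNP-array data on
    the X chromosome. Provides sex-aware quality control with pseudo-autosomal
    region (PAR) detection from male heterozygosity, extreme runs-of-homozygosity
    island (eROHi) scans in diploid females, integrated haplotype score (iHS) and
    nSL scans on phased haplotypes with frequency-bin standardization and sliding
    window outlier aggregation, the Haplotype Richness Drop (HRiD) statistic on
    hemizygous male haplotypes, and median-joining networks that classify swept
    haplotypes as ancestral or derived against an outgroup. Includes a
    founder-mosaic synthetic-data generator with injectable hard sweeps so every
    scan is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
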