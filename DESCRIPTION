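Package: gtcomp
Title: Fast All-vs-All Genotype Discordance for Sequencing Sample Identity QC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sample-identity quality control for DNA/RNA sequencing cohorts by
    all-vs-all genotype comparison. Genotypes at a BED-defined panel of common
    single-nucleotide variant positions are read from VCF files, encoded one
    byte per position as uppercase IUPAC nucleotide codes (ASCII NUL for
    missing), and every sample pair is compared with three bytewise Boolean
    operations (XOR, OR, AND) plus four closed-form count equations, yielding
    a symmetric discordance-rate matrix that exposes sample swaps, duplicates
    and hidden relatedness. Includes a Hardy-Weinberg synthetic-cohort
    simulator (technical replicates, genotyping error, missingness, planted
    label swaps), summary plots (discordance distribution, manifest-ordered
    heatmap, per-sample variant-allele-fraction plots) and a command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    vcfR,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
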