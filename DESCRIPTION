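Package: poolgp
Title: Genomic Prediction and GWAS from Pooled-DNA Sequencing of Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic selection programs that sequence phenotype-tail
    DNA pools instead of individuals. Implements pool construction from
    trait tails plus a random interquartile pool, allele-frequency estimation
    from pooled read counts on the 0-2 scale, depth- and MAF-based SNP
    filtering calibrated from technical replicates, a joint VanRaden realized
    additive relationship matrix over pools and individuals, GBLUP with
    heterogeneous per-environment residual variances fitted by REML,
    kinship-corrected single-marker association with Benjamini-Hochberg FDR
    control, and a direction-aware Fisher combination of two association
    scans. A breeding-population simulator with linkage, truncation
    selection, genotype-by-environment interaction, and pooled-read
    generation supports testing of every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
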