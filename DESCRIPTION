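Package: clinepool
Title: Pool-Seq Analysis of Clinal Population Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pooled-sequencing (pool-seq) allele count
    data along environmental clines. Reads PoPoolation2-style sync files,
    applies coverage and allele-count SNP filters, computes pool- and
    coverage-corrected nucleotide diversity (pi), Watterson's theta and
    Tajima's D, pairwise pi-based F_ST at SNP, gene and window level, calls
    candidate SNPs by combining empirical F_ST outlier scans with Fisher
    exact tests under FDR control, profiles the decay of significance around
    candidates, classifies SNP effects from gene models, performs
    gene-length-corrected Gene Ontology enrichment by SNP-resampling
    permutation, quantifies the contribution of chromosomal inversions, and
    classifies clinal allele-frequency trajectories with exact binomial
    confidence limits. Includes a synthetic-data generator emulating a
    three-population latitudinal design with known truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
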