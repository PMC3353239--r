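Package: neosex
Title: Male-Versus-Female Comparative Genomics of Young Neo-Sex and B Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for detecting early neo-Y chromosome
    degeneration and candidate B-chromosome sequence from sex-separated
    short-read data. Provides a deterministic synthetic-data generator
    (sexed diploid haplotypes, gene models, paired reads, truth tables), a
    minimal paired-end seed-and-extend aligner, pileup-based SNP and short
    indel calling with sex-partition classification, mate-pair-violation
    structural-variant scanning (insertions, deletions, tandem and dispersed
    duplications), neo-X/neo-Y allele reconstruction with premature-stop and
    frameshift pseudogene detection, Nei-Gojobori Ka/Ks and codon-usage bias
    indices, synteny-guided super-scaffolding with N50 accounting, and
    male-specific assembly subtraction with probe baiting for B-chromosome
    candidates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
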