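Package: divaria
Title: Genetic Variation and Expression Divergence Between Two Closely
    Related Plant Varieties
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A comparative-genomics toolkit for two closely related plant
    varieties (e.g. a grain and a sweet sorghum cultivar) sharing one
    reference annotation. Applies per-variety variant calls (SNP, indel,
    structural variant) to gene models and detects premature stop codons;
    estimates Ka/Ks by the Nei-Gojobori (1986) counting method with a
    normal test for Ka > Ks; identifies tandem and segmental gene
    duplications by transitive-closure family clustering and collinear
    anchor chaining; detects full-length CACTA DNA transposons by
    terminal-inverted-repeat pairing with target-site-duplication checks
    and LTR retrotransposons by a direct-repeat scan; classifies
    microarray expression divergence into six classes (variety-specific,
    two-fold, sucrose-regulated-only) with abundance binning and
    delta-delta-CT confirmation; analyses promoter variation, IUPAC
    cis-element frequencies and bisulfite methylation; and ties
    duplication modes to expression divergence through a pooled
    two-proportion u statistic. A seeded synthetic-data generator builds
    two-variety genomes with fully known ground truth so every step is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    igraph,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
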