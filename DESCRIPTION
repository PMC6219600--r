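Package: dartpoly
Title: Progenitor Inference for Allopolyploids from DArT-Style
    Presence/Absence Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing genotyping-by-sequencing marker tables of
    the kind produced by the DArTseq platform for polyploid species
    complexes such as the Aegilops-Triticum group. Reads dominant
    (SilicoDArT, presence/absence) and codominant (SNP, 0/1/2) marker
    matrices, applies call-rate filters, derives species-specific marker
    sets, scores diploid-to-polyploid marker retention to infer the
    diploid progenitors of allopolyploid genomes, screens diploid
    analyzers by subgenome homoeology against a hexaploid reference,
    builds per-chromosome retention profiles, and reconstructs species
    relationships by UPGMA clustering on the d = 100(1 - r) Pearson
    correlation distance with Newick output. A synthetic-data module
    simulates marker matrices with known ancestry so the whole pipeline
    can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
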