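Package: magcurate
Title: Curation of Low-Abundance Eukaryotic Genomes from Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Decision procedures for recovering and curating low-abundance
    eukaryotic symbiont genomes from metagenomic assemblies: majority-vote
    lowest-common-ancestor taxonomy of bins from protein homology hits,
    single-copy-marker completeness and contamination estimation with a
    quality gate and per-taxon deduplication, detection and merging of
    same-genome bins arranged as a constant-coverage GC "linear cloud",
    coverage-ratio enrichment quantification between preparation protocols,
    a three-step secretome classification cascade with small-secreted-protein
    calling and family count matrices, and a rescue search for gene families
    reported missing from a genome. A seeded synthetic-community generator
    with full truth tables supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
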