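Package: mitorg
Title: Comparative Mitogenome Organization, Control-Region Annotation and
    Gene-Tree Topology Typing for Anemonefishes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative organization analysis of annotated
    circular mitochondrial genomes, built around the eight published
    anemonefish (Pomacentridae: Amphiprioninae) mitogenomes. Parses
    GenBank flat files into gene tables with incomplete stop-codon
    classes (T-/TA-), signed intergenic spacers and gene-order
    signatures; summarises nucleotide compositions across genome sets
    with a one-way ANOVA test for compositional (anti-G) bias and
    pairwise identities; dissects the control region (D-loop) into
    TAS, central conserved domain and conserved sequence block (CSB)
    domains using consensus motifs with gapped spacers, detects
    TAS/cTAS hairpin pairs and tandem-repeat arrays with fractional
    copy numbers; and classifies rooted gene trees into four topology
    types defined by the position of Premnas biaculeatus relative to
    the percula complex. A seeded simulator generates synthetic
    mitogenomes, D-loops, alignments and trees with full ground-truth
    bookkeeping, and a pipeline driver emits the report bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn,
    withr
Config/testthat/edition: 3
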