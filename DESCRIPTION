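Package: luxcensus
Title: Genome-Wide Census of LuxI/LuxR Quorum-Sensing Gene Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects and classifies acyl-homoserine-lactone (AHL)
    quorum-sensing gene circuits in annotated bacterial genomes.  From a
    per-genome bundle of protein sequences (FASTA), gene coordinates (GFF3)
    and protein-domain hit tables (HMMER3 domtblout or InterProScan TSV),
    the package authenticates LuxR and LuxI homologs with a two-tier
    Pfam/InterPro signature rule engine, classifies their genomic
    arrangements (canonical luxI/R pairs, luxR solos, luxI solos, and
    convergent double luxR-luxR-luxI loci with gene-neighborhood topology
    typing), profiles conserved residues against TraR/TraI-style reference
    numbering, computes pairwise percent-identity matrices, and aggregates
    per-genome and per-genus census tables.  A synthetic-genome generator
    with planted ground truth supports end-to-end validation without any
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    dplyr,
    tibble,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
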