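Package: mut2func
Title: From Genome Mutations to Functional Consequences in Small Fungal Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to go from a list of candidate mutations in a compact
    (fungal) genome to their predicted functional consequences, and to the
    quantitative follow-up assays used to confirm them. Implements
    genomic-context filtering of variant calls (window GC, linguistic
    complexity, k-mer uniqueness), gene-element assignment with asymmetric
    promoter/terminator scan windows, exact genomic to spliced-CDS coordinate
    arithmetic with codon indexing, consequence prediction for SNVs and
    indels including frameshift novel-peptide and premature-stop accounting,
    protein-level characterization of truncated products (Guruprasad
    instability index, Bjellqvist isoelectric point, heptad coiled-coil scan,
    domain-loss report), a synthetic confocal-image simulator with
    nucleo-cytoplasmic ratio quantification, and efficiency-corrected qPCR
    expression ratios with a randomization significance test. A synthetic-data
    generator produces genomes, gene models, planted variants and assay data
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    GenomicRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
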