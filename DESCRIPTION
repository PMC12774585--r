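Package: crisprDonor
Title: Design of CRISPR/Cas9 Deletion and Endogenous Tagging Constructs
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Offline design of CRISPR/Cas9 gene-deletion and
    endogenous-tagging experiments for annotated genomes. Scans SpCas9
    (NGG) target sites around the start or stop codon of a chosen
    isoform, counts genome-wide off-targets by exact mismatch search,
    ranks guides by a position-weight efficiency score, proposes
    amplification and sequencing primers in fixed distance windows
    around the cut site, extracts homology arms, introduces silent PAM
    mutations into the donor, assembles homology-directed-repair donor
    vectors carrying fluorophore/SspB fusion cassettes with a floxable
    3xP3-DsRed marker, simulates Cre/LoxP marker excision with
    reading-frame validation, and writes three annotated GenBank
    cloning maps per design (guide vector, unaltered locus, edited
    locus). Includes a seeded synthetic mini-genome generator so the
    full pipeline runs and tests without any network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: CRISPR, SequenceMatching, Alignment, FunctionalGenomics
RoxygenNote: 7.3.3
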