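Package: proteodeg
Title: Proteogenomic Peptide Databases, IP-MS Evidence Filtering and
    Tissue-Specific Differential Expression Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for proteogenomic workflows in non-model plants where no
    complete proteome is available. Builds peptide search databases from
    transcriptome contigs by multi-frame translation, stop-codon splitting
    and minimum-length filtering; aggregates peptide-spectrum matches into
    per-protein evidence (distinct peptides, spectral counts, sequence
    coverage) and applies spectral-count acceptance filters for
    immunoprecipitation mass spectrometry (IP-MS) interactor screens;
    annotates candidate contigs by best local-alignment hit against
    reference proteomes; classifies multi-tissue differential-expression
    results into common and tissue-specific categories with plasticity
    summaries. A seeded synthetic-data generator with serialized ground
    truth exercises every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
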