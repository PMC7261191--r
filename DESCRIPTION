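Package: enhancerCGI
Title: CpG-Island-Dependent Promoter-Like Characteristics of Transcribed Enhancers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for comparing transcribed enhancers and promoters
    according to CpG island (CGI) status. Implements a sliding-window CpG island
    caller, position weight matrix scanning of twelve core promoter elements with
    a localized-overrepresentation test, pairwise motif co-occurrence statistics
    based on one-sided hypergeometric tail sums, CAGE-tag derived metrics
    (sharp/broad dispersion index, tau tissue specificity, bidirectional
    transcription directionality), and ChIP-seq peak overlap metrics (maximum
    signal, binding-event density per kilobase). A synthetic-data module
    generates genomes with planted CGIs and motifs, CAGE tag tables, and
    narrowPeak files with known ground truth so every stage is testable
    end-to-end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
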