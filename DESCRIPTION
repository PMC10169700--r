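Package: florinet
Title: Differential Transcription-Regulatory-Network Analysis for Floral
    Induction Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers transcription regulatory networks (TRNs) from promoter
    motif evidence combined with coexpression, differential-expression and
    curated gene-list criteria, and compares the networks obtained under two
    condition contrasts (control vs induced, control vs flowered) with a
    hypergeometric test for transcription-factor-family enrichment among
    topologically distinguishing nodes.  Includes a FIMO-style position
    weight matrix scanner with exact dynamic-programming p-values, a
    self-contained negative-binomial Wald test for differential expression,
    a canonical k-mer survey genome-size estimator, and a fully seeded
    synthetic-data generator (genome, annotation, motifs with planted
    promoter sites, negative-binomial counts with planted regulatory
    structure, error-free reads) so that every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
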