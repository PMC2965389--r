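Package: attenuscan
Title: Screening Bacterial Genomes for Rho-Independent Terminators and
    Transcriptional Attenuators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects Rho-independent (intrinsic) transcription terminators in
    the intergenic regions of annotated bacterial genomes using a trainable
    profile scorer with a descriptor-based fallback, classifies hits into 5'
    (leader) and 3' terminators, applies orientation and distance filters to
    nominate transcriptional attenuator candidates, scores gene families for
    attenuation propensity with phylogeny-aware normalized scores and Fisher
    exact enrichment tests, and clusters candidate leader sequences into
    putative regulons, including mobile (insertion-sequence derived)
    attenuators.  A synthetic-genome generator with planted ground truth
    supports end-to-end validation without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    withr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
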