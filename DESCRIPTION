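Package: wrkymeth
Title: Cytosine Methylation Effects on WRKY Transcription-Factor DNA Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how 5-methylcytosine represses WRKY transcription
    factor binding to W-box DNA elements along three complementary lines of
    evidence. First, it compares DAP-seq (native, methylated DNA) against
    ampDAP-seq (PCR-amplified, methylation-free DNA) signal at bound regions:
    normalized log10 signal ratios, best-binding-site discovery with a
    position weight matrix, methylation density, and per-motif-position
    Pearson correlation between methylation probability and binding with
    Benjamini-Hochberg masking. Second, it simulates and fits 1:1 Bio-Layer
    Interferometry sensorgrams, estimating association/dissociation rates and
    the steady-state dissociation constant for methylated and unmethylated
    W-box duplexes. Third, it analyses structure ensembles for van der Waals
    contacts and steric clashes between the W-box position-4 cytosine and the
    conserved WRKY-domain tyrosine, including in-silico C5 methylation. A
    synthetic-data module generates peak sets with planted methylation
    effects, sensorgrams from a ground-truth kinetic scenario registry, and
    idealized base-pair/tyrosine geometry fixtures, so every analysis is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    minpack.lm,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
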