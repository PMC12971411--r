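Package: panfam
Title: Pan-Genome Gene-Family Evolution Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the evolution of a gene family across a
    plant pan-genome: identification filters (domain E-value, sequence
    identity, PSPG-motif typing), orthogroup occupancy classification into
    core/soft-core/dispensable/private categories with pan/core saturation
    curves, gene duplication mode assignment under the priority cascade
    WGD > tandem > proximal > transposed > dispersed with an internal
    collinearity chainer, Nei-Gojobori (1986) Ka/Ks estimation with
    selection-class calls, structural-variant filtering and
    presence-expression association, promoter cis-element comparison, and
    TPM-based expression-dosage analysis. Includes a fully self-contained
    synthetic pan-genome generator with known ground truth so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
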