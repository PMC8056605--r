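Package: multiGRN
Title: Multi-Omics Gene Regulatory Networks for Expression Prediction and
    Rare-Variant Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds transcription-factor to target-gene regulatory networks by
    fusing ChIP-seq binding evidence, protein-protein interactions and
    co-expression with the PANDA message-passing algorithm, optionally
    re-weighting motif edges by normalized Hi-C promoter contacts. Regulatory
    geometry is strand-aware: CTCF-bounded cis-regulatory windows, promoters,
    introns and distal regions around the longest-transcript TSS. Network edge
    weights feed elastic-net models of log-expression whose averaged
    coefficients yield per-TF activator/repressor effect estimates, which in
    turn weight rare variants (via binding-disruption z-scores) in a
    sequence kernel association test (SKAT). Includes a FIMO-style PWM scanner
    with exact dynamic-programming p-values, a TEPIC-style distance-decay
    affinity score, and a self-consistent synthetic-data generator so the
    whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
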