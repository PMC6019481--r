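Package: pathprotect
Title: Pathway Protection Analysis of Two-Channel Microarray Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for quantifying how a treatment protects functional
    pathways against a transcriptomic insult, using two-channel microarray
    data in a multiple-yellow design (differently labeled biological
    replicates co-hybridized on each array). Implements spot validity
    filtering, per-label median normalization, redundancy averaging and
    iterative cross-condition renormalization; per-gene differential
    expression with a flexible fold-change cut-off (CUT) combining
    technical and biological variability, a heteroscedastic t-test with a
    Bonferroni-type correction for redundant spots, and ON/OFF calls;
    pathway-level quantifiers (percent regulated, Weighted Pathway
    Regulation, Transcriptomic and Pathway Protection); and expression
    coordination networks (Pearson correlation across biological
    replicates, synergistic/antagonistic/independent classification and
    coordination switches between conditions). A synthetic-data generator
    with planted ground truth supports parameter-recovery testing of the
    whole pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
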