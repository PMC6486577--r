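Package: recseq
Title: In Vitro Selection Profiling of Site-Specific Recombinase DNA Specificity
Version: 0.1.0
Authors@R: person("Rec-seq", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling the DNA specificity of site-specific
    recombinases (Cre, evolved Cre variants, and related enzymes) from
    in vitro selection experiments read out by high-throughput sequencing.
    Implements core-anchored gap-free read extraction with a mismatch
    filter, per-position canonical-base enrichment scores and per-base
    log2 enrichment matrices, UMI-based experiment quality scoring
    (kappa), replicate-level significance testing, and enrichment-driven
    genomic pseudosite (off-target) scanning. A selection simulator with
    a closed-form expected-enrichment oracle provides ground-truth data
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
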