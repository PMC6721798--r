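Package: ftlreg
Title: Dual Translational Repression of Ferritin Light Chain mRNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of the dual translational repression of
    ferritin light chain (FTL) mRNA by iron regulatory proteins (IRP) and
    eIF3. Implements a three-state occupancy model of the FTL 5'-UTR with
    an error-propagated Monte-Carlo test of mutually exclusive binding,
    mass-action simulation of competition electrophoretic mobility shift
    assays with dissociation-rate (k_off) and IC50 estimation, annotation
    of 5'-UTR regulatory elements and hyperferritinemia variants including
    the cap-distance steric rule, and seeded synthetic-data generators for
    reporter and binding assays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
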