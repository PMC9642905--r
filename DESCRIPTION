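Package: endodomain
Title: Quantification of Endosomal Membrane Microdomains in Coelomocyte Micrographs
Version: 0.1.0
Authors@R:
    person("Endodomain", "Developers", email = "endodomain@example.org",
           role = c("aut", "cre"))
Description: Quantifies sorting microdomains on the limiting membrane of
    large endosomes in C. elegans coelomocytes from multi-channel
    fluorescence micrographs. Implements circumferential line-scan
    profiling of endosome rings (microdomain spread), membrane-to-cytoplasm
    intensity ratios from paired measurement discs, an equal-area
    interior/peripheral log2 intensity ratio, thresholded Pearson
    colocalization, FRAP recovery-curve normalization and
    single-exponential fitting, skeleton-based fiber length, and an
    IWN-repeat motif scanner with BLAST-hit filtering for homolog curation.
    A fully parametric synthetic coelomocyte scene generator provides
    ground truth so that every metric is validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
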