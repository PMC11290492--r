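Package: baitjoin
Title: Bait-Anchored Junction Calling and Repair-Outcome Analysis for
    V(D)J Recombination Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates, calls, classifies, and summarises double-strand-break
    repair junctions from bait-anchored (LAM-HTGTS-style) sequencing libraries of
    a toy antigen-receptor locus. Provides a synthetic-library generator with
    ground truth (per-end resection, microhomology/direct/insertion joint
    structure, coding- vs signal-end usage, deletional vs inversional V usage,
    rejoins, and translocations), a k-mer-seeded two-changepoint junction
    caller emitting tab-delimited tlx junction records, a junction classifier (category, end
    type, configuration, joint structure, resection offset, sub-TAD), and the
    per-library summary statistics used in junction-level studies of
    non-homologous and alternative end joining: V-J efficiency, CE/SE ratio,
    41-bin junction-structure distributions, resection enrichment around RSS cut
    sites, sub-TAD usage, and relative/absolute translocation frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
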