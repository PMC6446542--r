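Package: nslchrom
Title: Promoter Nucleosome Organization, AT-Content Targeting, and TSS
    Selection Analysis for NSL-Complex Chromatin Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline of analyses for studying how a promoter-bound
    chromatin complex (the NSL complex of Drosophila) maintains phased
    nucleosome arrays, is targeted by AT-rich sequence, and governs
    transcription start site (TSS) selection and transcriptional noise.
    Provides a synthetic-data generator with known ground truth emulating
    MNase-seq fragments, ChIP enrichment tracks, CAGE-like 5'-end TSS
    counts, in vitro DNA-binding enrichments, and single-cell count
    matrices; promoter-anchored nucleosome occupancy, +1-nucleosome calling
    and shift estimation; windowed ChIP enrichment with k-means promoter
    classification and peak-overlap statistics; an AT-content logistic
    predictor of binding with cross-validated per-window slope tests and an
    all-5-mer partial-correlation screen; dominant-TSS calling, TSS spread,
    differential TSS usage (G-test) and 5'UTR length-change classification;
    and a permutation test for differential transcriptional noise on
    mean-trend-corrected CV2 residuals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    data.table,
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
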