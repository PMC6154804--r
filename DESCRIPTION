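Package: acylscape
Title: Multi-Mark Histone Acylation Landscapes from ChIP-Seq and RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates genome-wide profiles of histone lysine butyrylation
    (Kbu), crotonylation (Kcr), and H3K9 acetylation (H3K9ac) with matched
    expression data. Quantifies tag density (TPM) over gene bodies and
    promoters, calls marked genes from replicated peak sets, classifies the
    eight combination categories of the three marks, computes per-gene
    acylation proportions on the simplex, calls differential modification
    (replicate-consistent fold change), differential expression, and diurnal
    rhythm under fixed thresholds, and tests enrichment of mark combinations
    in stress-responsive and diurnal gene sets. Ships a synthetic-data
    generator that emulates the statistical structure of a rice seedling
    multi-mark study (TSS-proximal enrichment, mark co-occurrence,
    mark-coupled expression, planted differential and diurnal genes) with
    truth tables for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    data.table,
    limma,
    jsonlite,
    rlang,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
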