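Package: stpheno
Title: Spatiotemporal Projection of Bulk Transcriptomes onto Embryo Reference Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Projects bulk RNA-seq transcriptomes of in vitro differentiated
    cells onto a spatially resolved embryo reference atlas by Pearson
    correlation over a spatially informative gene set, and quantifies
    condition-versus-control divergence per spatial position with the
    phenotypic difference index (PDI), the per-position difference in
    correlation between sample groups. Includes TPM normalization with
    exon-union gene lengths from a GTF, pseudo-bulk Spearman comparison
    against single-cell references, corn-plot style rendering of correlation
    and PDI maps, and a ground-truthed synthetic atlas/bulk generator so the
    whole framework is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    GenomicRanges,
    IRanges,
    jsonlite,
    Matrix,
    optparse,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
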