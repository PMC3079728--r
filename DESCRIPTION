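Package: genebodymarks
Title: Gene-Body DNA Methylation and Histone-Mark Co-Occupancy on Tiling Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline relating gene-body DNA methylation enrichment
    signals (MIRA/UMC tiling arrays) to intragenic histone marks (H3K36me3,
    H3K9me3, H3K27me3, H3ac, H4K20me3). Parses gene models (BED12/refFlat)
    and probe-level log2-ratio tracks, derives promoter/gene-body/flank
    regions and CpG density per kilobase, classifies genes by positive-probe
    coverage, counts mark co-occupancy with chi-square and Fisher exact
    tests, computes strand-oriented 40-bin composite (metagene) profiles and
    clustered heatmap matrices, summarises marks at exon/intron resolution
    stratified by expression, and classifies wild-type versus
    DNMT-knockout expression changes. Ships a deterministic synthetic-data
    generator that plants gene classes (methylated active, ZNF-like,
    Polycomb-repressed, inert) on a chromosome-scale probe grid for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    ggplot2
Config/testthat/edition: 3
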