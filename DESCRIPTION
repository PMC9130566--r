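Package: poolscan
Title: Pool-Seq Allele-Frequency Genome Scans and Parallelism Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome scans for local adaptation from pooled sequencing data.
    Reads Popoolation2 sync allele counts, applies count-level SNP filters,
    computes standardized allele-frequency differences (dAF) between
    anadromous and freshwater pools in 20-SNP sliding windows, calibrates
    outlier thresholds with a label-permutation null, merges outlier windows
    into genomic regions with gene annotation, and quantifies parallelism
    across populations and lineages (shared outlier regions, shared
    polymorphism, cross-lineage convergence heat maps, a shared
    nonsynonymous-site percentile test). Includes windowed pool-seq
    population genetics (pi, Watterson's theta, Tajima's D, dxy) and a
    synthetic multi-lineage pool-seq generator with known truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
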