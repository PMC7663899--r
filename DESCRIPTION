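Package: wgaqc
Title: Rank Whole-Genome-Amplification Quality of Single Cells from Shallow Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks the amplification quality of single cells subjected to
    whole-genome amplification (e.g. multiple displacement amplification, MDA)
    using shallow (<1x) sequencing. Phased heterozygous germline SNPs are
    pooled into coverage-scaled SNP units; the dispersion (standard deviation)
    of the per-unit haplotype allele frequency and the allelic dropout rate
    quantify amplification uniformity, classify cells as good, moderate or
    bad, and rank them for selection prior to deep sequencing. Includes a
    pileup-based allele counter for BAM input, a MAPD baseline metric, and a
    fragment-level MDA amplification-bias simulator so the whole workflow can
    be exercised and validated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    Rsamtools,
    GenomicRanges,
    IRanges,
    ggplot2,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
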