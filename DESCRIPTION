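Package: chipnet
Title: Symmetric-Null Probe Statistics and Promoter Co-Occupancy for
    Non-Tiling ChIP-chip Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls transcription-factor-bound probes on two-channel
    promoter (non-tiling) ChIP-chip arrays using a symmetric-null
    statistic: probes below the identity axis of the input/IP scatter are
    taken as a reflected sample of the null, an intensity-dependent
    robust scale is fitted with a smoothing spline, and one-sided
    p-values are derived from normalized distances to the x=y axis.
    Technical replicates are combined with a fixed conjunction rule and
    genes are called through their best promoter probe.  Downstream
    stages build gene-by-factor occupancy matrices with hierarchical
    clustering and combination groups, TSS-distance binding profiles,
    integration with differential mRNA/miRNA expression (total gene
    signal, QC regression, pathway filtering), simplified k-mer/PWM motif
    enrichment with a chi-square homogeneity test, and 2^-ddCt qPCR
    quantification.  A synthetic-data generator with planted ground truth
    makes every stage testable offline.
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
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
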