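Package: cochip
Title: Co-Occupancy ChIP-Seq Quantification and Knockdown Dependency
    Analysis for the Ash1-Mrg15 Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream quantification for ChIP-seq co-occupancy studies of
    the Drosophila Ash1 histone methyltransferase complex and its Mrg15
    subunit. Provides depth-normalized read-density quantification (RP10M,
    RPM per kb), peak-set overlap and intensity correlation, metaprofiles
    and signal matrices around peaks, Mrg15-stratified comparison of
    H3K36me2 occupancy, knockdown dependency analysis by intensity stratum,
    first-exon gene scoring with super-target detection by cumulative read
    share, integration with expression fold changes, and Michaelis-Menten
    kinetics fitting for methyltransferase assays. A synthetic-data
    generator emulates the assumed statistical structure (nested peak sets,
    correlated intensities, condition-dependent tracks, planted super
    targets and expression responders) with a machine-readable truth set
    for closed-loop validation.
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
    rtracklayer,
    minpack.lm,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
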