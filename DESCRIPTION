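Package: StrainQuant
Title: Unique k-mer Normalized Strain Abundance Quantification for
    Defined Microbial Communities
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies per-strain relative abundance in defined (synthetic)
    microbial communities from shotgun metagenomic reads. Member genomes are
    split into N50-bounded subcontigs, canonical k-mers are hashed to count the
    uniquely mappable content of every subcontig, and perfectly and
    unambiguously mapped read pairs are normalized into FUKM (fragments per
    thousand unique k-mers per million mapped fragments). Per-strain point
    estimates are the median subcontig FUKM and a unique-k-mer-weighted
    percentile of subcontig FUKMs. Includes an exact paired-end mapper, a
    synthetic community and read simulator with six abundance distributions,
    and composition-recovery benchmark statistics (Jensen-Shannon divergence,
    coefficient of variation, log-scale Pearson correlation, presence/absence
    F1).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
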