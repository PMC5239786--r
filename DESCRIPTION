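Package: simmscan
Title: Simultaneous Mapping of Causal Mutations in Multiple Mutant Strains by
    Bulked Segregant Sequencing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies EMS-induced causal mutations simultaneously in multiple
    mutant strains derived from one parental line, from pooled F2
    (bulked-segregant) sequencing data. Each strain is scored against all other
    strains as background: an allele index (AI) removes shared polymorphisms
    and sequencing noise, the SNP index (SI) and the sixth power of a Euclidean
    distance between test and background indices (ED^6) highlight linked
    candidate regions along loess-smoothed genome scans, candidate SNPs are
    ranked by predicted functional impact against gene models, dense
    still-segregating (heterologous) segments and sibling strains are detected
    and handled, and sites lost to GC-content coverage/quality bias inside a
    candidate region can be rescued by per-GC-group depth and quality
    correction. Includes a synthetic multi-strain F2-bulk data generator with
    known ground truth so the whole pipeline is testable without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
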