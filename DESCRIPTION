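Package: retroinvade
Title: Detecting and Dating Transposable Element Invasions from
    Time-Stamped Short-Read Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to detect and date transposable-element (TE) invasions
    from short-read genome samples collected at different times. Estimates
    haploid TE copy numbers by normalizing TE coverage to single-copy-gene
    coverage, calls TE-internal SNPs and summarizes cross-sample TE
    composition by principal component analysis with diagnostic-SNP
    detection, classifies per-sample invasion status and assembles invasion
    timelines, computes piRNA ping-pong signatures from small-RNA reads,
    and scores candidate horizontal-transfer donor assemblies by repeat-hit
    similarity. Includes a synthetic-data generator that produces genomes,
    short-read and small-RNA samples, and donor-assembly panels with known
    ground truth, so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ggplot2,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    cluster,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
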