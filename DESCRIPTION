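Package: cnvdosage
Title: Genome Size, Copy Number Variation and Dosage Compensation from
    Depth and Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing heritable genome size variation driven by
    gene copy number variation (CNV) in haploid micro-algae and similar
    systems. Estimates nuclear genome size from k-mer frequency histograms
    with organelle-peak subtraction, calibrates flow-cytometry genome sizes
    against an internal standard and partitions F1 genome-size variance into
    between- and within-line components, calls per-ortholog-group CNV from
    depth-per-million log-ratios with depth-dependent thresholds, classifies
    dosage response of expression (compensated, inverse, positive,
    proportional) from paired DNA/RNA depth, classifies duplication origin
    from bootstrap-supported monophyly in gene trees with an NG86 Ks paralog
    filter, and tests GO-term enrichment. A synthetic-data generator
    reproduces the statistical structure of every input so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
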