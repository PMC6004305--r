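Package: methscape
Title: Whole-Genome Bisulfite Sequencing Methylome Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for plant whole-genome bisulfite sequencing:
    enumerates reference cytosines by sequence context (CG, CHG, CHH) on both
    strands, extracts per-site methylated/unmethylated read counts from
    bisulfite alignments, calls methylated sites with a binomial test against
    the conversion-failure rate, summarises the methylome (per-context mC
    fractions, methylation-level histograms, 9-bp neighbourhood composition,
    metagene and transposable-element profiles, expression-stratified
    profiles), detects differentially methylated regions between two samples
    with a five-criterion caller (site chaining, coverage, length, fold
    change, Pearson chi-square), associates DMRs with gene/TE upstream, body
    and downstream zones, and cross-references DMR genes with differential
    expression and 24-nt siRNA loci. Includes a full bisulfite-data simulator
    (genome, annotations, stage-specific methylomes with spiked DMRs, count
    tables, aligned reads) with machine-readable ground truth for recovery
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
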