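Package: bsmv
Title: Condition-Specific Effects of Transcription Factor Binding Site Motif Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transcription factor binding site motif variants (BSMVs)
    whose target genes show condition-specific expression patterns, from a
    normalized gene-by-condition expression matrix and genome-wide binding
    site annotations. The core statistic compares Euclidean distances between
    rank-transformed expression profiles of genes carrying the same versus
    different nucleotides at one motif position (the variant distance of
    ranked experiments, VDRE), assessed by gene-label permutation with
    Storey q-value FDR estimation. Downstream characterization includes an
    experiment-type clustering score with its own permutation test, rank
    reversal and slope-sign tests separating allosteric from pure affinity
    effects, permutation-based GO process enrichment, a Fisher exact screen
    for confounding secondary binding sites, motif position information
    content under a non-uniform genomic background, and alignment-column
    diversity summaries with Wilson confidence intervals. A synthetic data
    generator with planted BSMV-by-condition effects provides ground truth
    for every statistic, and a pipeline driver runs all stages reproducibly
    with a machine-readable manifest.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
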