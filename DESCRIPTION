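Package: founderscan
Title: Founder Events, Relatedness and Mutation Dating from
    Identity-by-Descent Segments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects identity-by-descent (IBD) segments in phased SNP data
    by windowed haplotype hashing, estimates pairwise degrees of
    relatedness from genome-wide IBD sharing, builds locus-anchored
    relatedness networks to resolve founder events, extracts the shared
    founder haplotype of each cluster, and dates mutations with the
    Gamma method for time to the most recent common ancestor. A bundled
    gene-dropping simulator generates phased cohorts with founder
    clusters, relative pairs of known degree and unrelated background
    samples, together with truth tables for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    yaml,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'genetic-map.R'
    'vcf-io.R'
    'segments-io.R'
    'simulate.R'
    'ibd.R'
    'relatedness.R'
    'network.R'
    'founder.R'
    'dating.R'
    'pipeline.R'
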