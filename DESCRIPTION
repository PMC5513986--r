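Package: domesticscan
Title: Candidate-Gene Domestication Scans with Wild Versus Landrace Resequencing Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Population-genetic scan for signatures of purifying selection on
    candidate genes during crop domestication, built around a wild/weedy versus
    landrace resequencing contrast. Provides gene-level and single-nucleotide
    estimators of nucleotide diversity (theta-pi), Watterson's theta, Tajima's D,
    Hudson's Fst and the reduction-of-diversity (RoD) ratio; a three-criterion
    per-SNP selection classifier calibrated against a neutral-locus RoD baseline;
    synonymous/non-synonymous SNP annotation against the standard genetic code;
    seed-preferential expression classification with a 2x2 chi-square enrichment
    test; bidirectional-best-hit plus synteny ortholog merging; and
    minimum-spanning-tree haplotype networks. A two-population coalescent
    generator emulating a domestication bottleneck (with optional partial-sweep
    diversity loss at selected genes) produces fully synthetic FASTA/VCF/TSV
    inputs so the entire pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    ape,
    igraph,
    optparse,
    tools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
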