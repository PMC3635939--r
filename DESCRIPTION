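Package: lenspipe
Title: Transcriptome SNP Discovery, Divergence Dating, Array Design,
    Linkage Mapping and Synteny for 3'-cDNA Genotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-backed pipeline for 3'-anchored
    transcriptome SNP resources in inbred crop panels such as lentil (Lens):
    read-depth threshold SNP calling against reference contigs with a
    non-redundant multi-genotype merge, transition/transversion and
    codon-impact classification, Nei-Gojobori (1986) synonymous-substitution
    (Ks) estimation with mode-of-binned-values divergence dating,
    microsatellite (SSR) detection, candidate selection for fixed-content
    genotyping arrays with KASP-style flank extraction, recombinant inbred
    line (RIL) linkage-map construction (LOD grouping, Kosambi distances),
    and synteny chaining against a model genome by weighted longest
    increasing subset. A synthetic-data module generates every input with
    known ground truth so each stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    seqinr,
    jsonlite,
    optparse
Config/testthat/edition: 3
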