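Package: panwga
Title: Reference-Free Pangenome Alignment and Polymorphism Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds reference-free whole-genome multiple alignments of
    chromosome-level assemblies by block anchoring, chaining, reference
    rotation and gap resolution, yielding a pangenome coordinate system (a
    matrix of corresponding positions). From the alignment it extracts SNPs
    and presence/absence structural variants, classifies structural variants
    as simple or complex by an allele-length rule, infers indel polarity from
    presence-allele frequency, discovers mobile elements through a graph of
    sequence nestedness, computes pan/core saturation curves and coordinate
    dilation, and audits reference bias with a six-way SNP-call taxonomy and
    expression/methylation concordance rules. A synthetic-pangenome simulator
    with a machine-readable truth ledger makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
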