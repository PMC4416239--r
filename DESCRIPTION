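Package: rrascan
Title: Detection and Annotation of Rare Reference Allele Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: The human reference assembly carries tens of thousands of loci
    at which the reference base is a rare allele (population frequency below
    1%), so standard resequencing pipelines silently miss the variant that
    most individuals actually carry. rrascan builds a catalog of such rare
    reference allele (RRA) loci from a multi-sample population VCF,
    classifies each locus by how often the reference allele is observed
    (never / only heterozygous / also homozygous), genotypes the catalog in
    new samples with a forced-allele Bayesian diploid caller, emits germline
    and somatic (tumor/normal, Fisher-tested) RRA variant calls, and
    annotates calls with genomic features, conservation scores, regulatory
    evidence and gene-phenotype links. A synthetic-data module generates
    every input the pipeline consumes at toy scale with planted ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
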