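Package: pileupCall
Title: Probabilistic Genotype and SNP Calling from Sequencing Pileups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A generative probabilistic model for genotype and SNP calling
    from next-generation sequencing pileup data. Per-read base and mapping
    qualities are converted into base-call distributions, combined with a
    structured substitution-error matrix and an optional ancient-DNA
    cytosine-deamination damage model, and marginalised exactly to a
    posterior distribution over haploid or diploid genotypes under a
    Hardy-Weinberg genotype prior. Includes a samtools mpileup -s parser,
    a VCF writer, post-hoc quality-control filtering, a simple two-allele
    indel caller, call-set evaluation metrics, and a seeded read/pileup
    simulator with end-clustered deamination damage for end-to-end testing
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    Biostrings,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
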