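Package: hopaudit
Title: Flagging Index-Hopping Artefacts in Multiplexed Tumour Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing somatic single-nucleotide variant calls for
    artefacts caused by sample-index misassignment (index hopping) in
    multiplexed Illumina sequencing pools. For every somatic call the package
    computes the pool-complement allelic fraction (PC-AF): the fraction of
    reads supporting the variant among all co-multiplexed samples from other
    individuals. Calls are classified as apparently true, suspected
    contaminant, or ambiguous by combining PC-AF with a population cohort
    allele frequency. The package also ships a pileup-level simulator of
    index hopping and of deliberate read admixtures with per-read origin
    truth, and a method-of-moments estimator of a sample's total contaminant
    read fraction from allele counts at homozygous population marker sites,
    so the whole workflow can be validated end-to-end on synthetic pools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
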