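Package: recessmap
Title: Homozygosity Mapping and Variant Prioritisation for Recessive
    Disease Loci in Livestock
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping fully penetrant recessive Mendelian defects
    in livestock populations with a strong founder effect. Implements
    homozygosity mapping from SNP-array genotypes of affected and control
    animals (per-marker affected genotype counts, control allele
    frequencies with extreme-value reporting, a Hardy-Weinberg
    likelihood-ratio statistic, and detection of the shared homozygous
    interval), a Mendelian-consistency variant prioritisation cascade over
    whole-genome variant calls with coding-consequence annotation, and the
    design of a haplotype-based indirect carrier test. A gene-drop
    pedigree simulator reproduces the statistical structure of such a
    study (a founder recessive mutation on a shared haplotype, chip
    genotypes for an affected/control cohort, and a variant table for a
    sequenced family quartet) so the whole pipeline can be exercised and
    validated without external data.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
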