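Package: ervtrace
Title: Pedigree-Aware Analysis of Endogenous Retrovirus Dynamics
Version: 0.1.0
Authors@R:
    person("ervtrace", "maintainers", email = "ervtrace@example.org",
           role = c("aut", "cre"))
Description: Tools to study ongoing retroviral germline colonization in
    pedigreed host populations, motivated by the koala retrovirus (KoRV)
    and the older phaCin-beta lineages. Implements integration-site
    discovery from anchored-mate and soft-clipped short-read evidence,
    read-ratio zygosity genotyping with a binomial missingness model,
    triad-based detection of new and eliminated germline integrations,
    trio germline mutation-rate estimation with LTR-divergence molecular
    dating, long-read inverse-PCR integration calling, and odds-ratio
    weighted genetic risk scores with bootstrap cutoff selection. A
    synthetic cohort generator with full truth tables makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    S4Vectors,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
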