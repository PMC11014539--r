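Package: apobecsmoke
Title: APOBEC Mutagenesis Characterization in Smoking-Associated Lung Cancer Genomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-sample characterization of APOBEC3 mutagenesis from somatic SNV
    catalogs: pyrimidine-normalized sequence-context annotation, TCW-motif
    enrichment with a one-sided Fisher exact test and a minimum APOBEC
    mutation-load estimate, clustered-mutation and kataegis detection with a
    negative-binomial cluster P-value and strand-coordinated ssDNA summaries,
    YTCA/RTCA tetranucleotide classification of APOBEC3A-like versus
    APOBEC3B-like phenotypes, the two-evidence low/high APOBEC subtype rule,
    clock-mutation tumor timing (MRCA age and latency), and Gamma-Poisson
    cell-of-origin inference from binned mutation densities. Includes a
    synthetic-cohort generator with machine-readable ground truth so every
    stage is testable without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    MASS,
    lme4,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
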