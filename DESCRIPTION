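Package: somaticALL
Title: Somatic Mutation, Clonal Evolution and Relapse Analysis for Pediatric ALL Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for somatic mutation call tables from
    targeted deep sequencing of acute lymphoblastic leukemia (ALL) cohorts.
    Provides allele-fraction based clonal/subclonal classification with a
    data-driven boundary between the clonal and subclonal AF peaks,
    trinucleotide mutational-signature extraction with panel motif-composition
    correction and non-negative matrix factorization, consensus driver-gene
    discovery from burden, functional-impact and positional-clustering
    statistics, competing-risks relapse association for genes and KEGG-style
    pathways via cumulative incidence and Gray's test, and paired
    diagnosis/relapse clonal-evolution classification (gained/lost/shared
    status, low-AF rescue of relapse-gained mutations, rising clones, and
    relapse-associated gene criteria). A synthetic cohort generator with full
    ground truth emulates the statistical structure of such cohorts so every
    stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    cmprsk,
    Biostrings,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
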