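Package: cobatlas
Title: Phenotyping, Quantification and Global Mapping of Cobamide-Producing Prokaryotes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies metagenome-assembled genomes (MAGs) by cobamide
    (vitamin B12 family) biosynthesis phenotype from profile-HMM hit tables,
    flags cobamide users, builds habitat-specific universal single-copy marker
    databases from producer genomes, converts mapped read counts into RPKM
    producer abundances, and runs the accompanying ecological statistics
    (rarefied diversity, Mantel tests, Wilcoxon volcano of pathway discovery
    rates, Spearman/FDR screens, nutrient-cycle aggregation) and a random-forest
    spatial prediction workflow with recursive feature elimination and
    cross-validated grid search. A synthetic-data module generates every input
    with known ground truth so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    vegan,
    randomForest,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'abundance.R'
    'cobatlas-package.R'
    'ecostats.R'
    'geomap.R'
    'io.R'
    'markerdb.R'
    'phenotype.R'
    'pipeline.R'
    'synthetic.R'
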