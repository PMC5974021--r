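Package: mitoABC
Title: Structured-Coalescent Simulation and Random-Forest ABC for mtDNA
    Demographic Inference
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for demographic inference from complete mitochondrial
    genome alignments. Implements descriptive population-genetic statistics
    (haplotype and nucleotide diversity, pairwise Phi-st, hierarchical
    AMOVA with permutation tests, Mantel tests, haplotype sharing), a
    single-locus structured-coalescent simulator with population splits,
    exponential growth, migration and a coding/noncoding two-partition
    mutation model, encodings of competing demographic scenarios for the
    origin of Tai-Kadai speaking populations in Mainland Southeast Asia,
    and approximate Bayesian computation model choice and parameter
    estimation with random forests (reference tables, LDA-augmented
    summaries, out-of-bag prior error rates, confusion matrices, votes,
    posterior probabilities, posterior parameter quantiles). Includes a
    synthetic-data generator so that every stage is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    MASS,
    ranger,
    geosphere,
    yaml,
    jsonlite,
    withr,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'stats-mantel.R'
    'io-alignment.R'
    'stats-distance.R'
    'stats-amova.R'
    'stats-diversity.R'
    'abc-summaries.R'
    'io-reftable.R'
    'abc-rf.R'
    'io-metadata.R'
    'mitoABC-package.R'
    'sim-demography.R'
    'sim-coalescent.R'
    'synthetic-data.R'
    'pipeline.R'
    'scenarios.R'
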