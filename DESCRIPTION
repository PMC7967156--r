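Package: thermosector
Title: Protein Sector Analysis and Thermostability Mutation Design from
    Multiple Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Primary-sequence-based design of thermostabilizing point
    mutations for a protein family. From a labeled multiple sequence
    alignment the package computes a residue correlation analysis (RCA)
    matrix from BLOSUM50-scored pairwise substitution events, identifies
    coevolving protein sectors by eigen-decomposition against a
    column-shuffling null with Gaussian-fit significance boundaries and
    k-means clustering in mode space, quantifies thermophile versus
    mesophile amino-acid usage divergence per position through a
    relative-entropy angle, and proposes ranked stabilizing single and
    double point mutations drawn from the thermophilic sequence profile.
    A synthetic alignment generator with planted covarying sectors and
    planted thermal divergence provides ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    mclust
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'substitution-model.R'
    'alignment-io.R'
    'coevolution.R'
    'sector-analysis.R'
    'profile-divergence.R'
    'mutation-design.R'
    'synthetic-msa.R'
    'pipeline.R'
    'thermosector-package.R'
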