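Package: famdpc
Title: Unsupervised Protein Family Discovery by Density Peak Clustering
    of Local Alignments
Version: 0.1.0
Authors@R:
    person("famdpc", "developers", email = "famdpc@example.org",
           role = c("aut", "cre"))
Description: Discovers putative protein domain families from an
    all-versus-all local-alignment table without supervision. Aligned
    regions are clustered per query by footprint overlap with Density
    Peak Clustering, primary clusters are metaclustered across queries
    by shared membership, density-split metaclusters are merged and
    size/length-filtered, and seed sets are pruned for profile-HMM
    construction via pluggable external-tool backends. Validation
    analytics compare metaclusters against reference domain
    annotations (dominant architectures, overlap classes), label
    metaclusters by residue composition, and fit a generalized Pareto
    tail to the family-size distribution. A synthetic proteome
    generator with planted families and a built-in Smith-Waterman
    aligner allows the full pipeline to run end to end at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    xml2,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
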