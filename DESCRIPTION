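Package: scrollsaw
Title: Backbone-Anchored Classification of Divergent Gene Families and
    Ancestral-Complement Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-phylogenomic toolkit for classifying members of
    highly divergent protein families across the eukaryotic tree, built around
    the Vps9-domain Rab5-subfamily guanine nucleotide exchange factors as the
    worked example. Candidate family members are identified by reciprocal-best-hit
    Smith-Waterman screening with a Karlin-Altschul E-value gate and annotated by
    position-specific scoring of domain blocks; candidates are profile-aligned
    onto a fixed curated backbone alignment, placed in distance trees with
    bootstrap supports, and assigned to subfamilies by backbone-anchored clade
    membership. A Scrollsaw reduction selects the shortest-branching
    (slowest-evolving) representative of each clade per lineage, normalised
    against a reference anchor, for deep phylogeny. Presence/absence matrices
    feed inference of the Last Eukaryotic Common Ancestor (LECA) gene complement
    and Dollo-parsimony mapping of gains and losses, including counts of
    convergent domain-architecture acquisitions. A gene-family evolution
    simulator with known ground truth supports end-to-end recovery benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
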