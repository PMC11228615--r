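Package: krstereo
Title: Stereochemical Prediction for Ketoreductase Domains of Modular cis-AT Polyketide Synthases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the stereochemical outcome (A/B/C type and epimerizing
    subtype 1/2) of ketoreductase (KR) domains from modular cis-AT polyketide
    synthases using fingerprint sequence motifs (LDD, W, H, P and newer
    companion motifs), stratified by taxonomic origin and module architecture
    (alpha/beta/gamma/delta modules). Queries are mapped onto a packaged
    reference coordinate system by global alignment so that motif positions
    are addressable by column; a rule engine converts the observed motif
    calls into a typed prediction with confidence tiers. A Neighbor-Joining
    phylogenetic fallback (Jukes-Cantor corrected protein distances, clade
    membership of the catalytic KR subdomain) supports cases the motifs leave
    ambiguous. Sequence-logo statistics allow motif re-derivation on user
    datasets, and a synthetic sequence generator provides labeled benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
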