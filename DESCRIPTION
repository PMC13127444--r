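Package: redoxtaxa
Title: Decision-Tree Mining of Widespread Taxa Along Deep-Sea Sediment Redox Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies "widespread taxa" in deep-sea sediment microbial
    communities by pairing family-level 16S community composition with
    pore-fluid redox chemistry (oxygen, nitrate, ammonium, divalent
    manganese). Implements compositional preprocessing (pseudo-count zero
    imputation, centered log-ratio transform, Aitchison distance),
    presence/absence screening with Storey q-value false-discovery-rate
    control, from-scratch CART regression and classification trees with
    Monte-Carlo cross-validated rule mining for taxon importance, dual-
    criterion selection of globally present high-importance taxa, and
    ordination (compositional PCA and distance-based redundancy analysis).
    A multi-area sediment-core simulator with depth-resolved redox zonation
    and planted metabolic guilds provides ground truth for parameter-
    recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart,
    vegan,
    jsonlite
Config/testthat/edition: 3
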