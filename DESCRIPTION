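Package: cmselect
Title: Connectivity-Map Compound Selection for Directed Stem-Cell
    Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks small molecules for directed stem-cell differentiation by
    transcriptional connectivity: a weighted Kolmogorov-Smirnov enrichment
    score matches each compound-treatment gene signature (paired sets of the
    most up- and downregulated genes) against a ranked stem-cell-versus-target-
    tissue differential expression profile, and the resulting combined scores
    produce a rank-ordered candidate list. Each candidate is annotated with
    protein targets predicted by a Laplacian-modified naive Bayes model over
    ECFP4 circular fingerprints trained on filtered bioactivity data, and with
    disease-relevance inference scores, yielding an integrated, mechanistically
    interpretable shortlist. Includes readers and writers for GCT, CLS, CHIP,
    GMT and tabular bioactivity formats, plus deterministic synthetic-data
    generators with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    fgsea,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
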