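Package: kopredict
Title: Reconstruction and Neural Prediction of KEGG Metabolic Modules
    from Incomplete Genome Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs KEGG metabolic modules from KEGG Ortholog (KO)
    gene annotations of bacterial genomes, and predicts the presence of
    modules that appear incomplete because the genome itself is incomplete
    (as is typical for metagenome-assembled genomes). Parses KEGG-style
    module definition strings into boolean step expressions, enumerates KO
    combinations that complete a module, evaluates completeness of a KO
    set, and suggests gap-filling KOs. Module presence is predicted with a
    pair of multi-label feed-forward neural networks partitioned by module
    prevalence, trained on presence/absence feature matrices; annotation
    downsampling simulates genome incompleteness, and an evaluation
    harness benchmarks the networks against two naive classification
    rules. A seeded synthetic module/genome generator makes the whole
    pipeline trainable and testable at desk scale.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
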