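Package: daisydrive
Title: Deterministic Simulation of Daisy-Chain and Homing Gene Drives
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete-generation, deterministic genotype-frequency recursion
    for CRISPR homing endonuclease gene drives, including self-perpetuating,
    split, and daisy-chain architectures. Models germline cutting with
    homology-directed repair and type-1/type-2 resistance allele formation,
    maternal Cas9/gRNA deposition with mosaic fitness costs, dominant and
    recessive sex-specific fitness, and two panmictic populations linked by
    migration. Provides drive-design presets, transition-matrix construction
    (germline conversion, embryonic deposition, selection, meiosis), trajectory
    metrics, and a parameter-sweep engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
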