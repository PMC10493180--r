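Package: ddifusion
Title: Multimodal Similarity Fusion for Drug-Drug Interaction Event Prediction
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts which of n drug-drug interaction (DDI) event types occurs
    for a drug pair from multiple binary drug feature modalities (mono side
    effects, targets, enzymes, chemical substructures, pathways). Per-modality
    Jaccard similarity matrices are concatenated into a drug feature table;
    a pair is encoded as the elementwise sum of its two drugs' rows and
    classified with a small fully connected neural network. Includes
    stratified and nested cross-validation, micro-averaged multiclass metrics
    with one-vs-rest AUROC/AUPR, leave-one-feature-out ablation, feature
    subset sweeps, PCA reduction scenarios, alternative pair encodings,
    per-modality model fusion, ranked false-positive tables, and a synthetic
    benchmark generator with planted latent-group structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
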