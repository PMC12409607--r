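Package: smilesaugment
Title: SMILES Data Augmentation Strategies for Chemical Language Models
Version: 0.99.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Implements five data-augmentation strategies for training
    generative chemical language models on SMILES strings: SMILES
    enumeration, token deletion (random, validity-enforced, and protected
    variants), atom masking (random and functional-group variants),
    BRICS-based bioisosteric substitution, and self-training.  Provides the
    LSTM next-token language model the strategies feed, temperature
    sampling, dataset curation with scaffold-stratified nested splits,
    similarity-stratified fine-tuning set selection, and a full evaluation
    suite (validity, uniqueness, novelty, descriptor-wise
    Kolmogorov-Smirnov distances, and Bemis-Murcko scaffold diversity and
    novelty).  Molecular-graph operations are delegated to RDKit through a
    bundled Python helper; all randomness is controlled from R.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
SystemRequirements: Python (>= 3.9) with the rdkit package on the PATH as
    'python' (or set options(smilesaugment.python=...)).
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
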