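Package: dsattn
Title: Double-Scale Attention Networks for Protein Sequence Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transformer-encoder protein sequence classifier with multi-scale
    1-D convolutional feature extraction and a probabilistic double-scale
    (spatial x positional) attention matrix built by a feature-agreement
    algorithm. Supports masked-language-model self-supervised pre-training on
    unlabeled amino-acid sequences, supervised fine-tuning for tasks such as
    enzyme-class prediction, attention-based motif interpretability analysis,
    and a planted-motif synthetic benchmark generator. Forward and backward
    passes are implemented in base R matrix algebra with an AdamW optimizer;
    no external deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
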