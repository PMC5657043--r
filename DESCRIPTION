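Package: epideep
Title: Enhancer Prediction from Epigenomic Features with Deep Belief Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts enhancer regions from DNA sequence composition and
    epigenomic signal. Candidate regions are featurized as strand-collapsed
    k-mer frequencies (k = 2..4), GC content, and per-region sums of DNA
    methylation and histone-modification signal tracks. A deep belief
    network is pretrained greedily from stacked restricted Boltzmann
    machines trained by contrastive divergence, then fine-tuned as a binary
    classifier with backpropagation. Includes stratified k-fold
    cross-validation, a feature-family ablation protocol, exact-enumeration
    oracles for small energy models, a synthetic genome/track simulator for
    end-to-end testing, and readers/writers for FASTA, BED and bedGraph.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
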