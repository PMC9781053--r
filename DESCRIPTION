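Package: pcenet
Title: Progressive Contextual Excitation Networks with L1-Norm Filter Pruning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains, prunes and audits Progressive Contextual
    Excitation Networks (PCENet): residual convolutional classifiers whose
    top-level representation is re-weighted by a contextual channel
    attention accumulated over the feature pyramid by a gated memory cell.
    Implements L1-norm structured filter pruning (rank filters by the sum
    of absolute kernel weights, drop the smallest, rebuild a genuinely
    smaller network) with fine-tuning to recover accuracy, plus model
    audits (per-layer dimensions, parameter counts, size estimates,
    latency harness), a seeded synthetic image-set generator for
    crop/seed-like classification tasks, and a command-line interface
    covering the full train-prune-finetune-evaluate-audit loop.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
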