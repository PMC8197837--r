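Package: copdGAN
Title: Conditional GAN Augmentation and Rule-Based Validation for COPD Vital Signs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for augmenting small Internet-of-Medical-Things vital-sign
    datasets collected from patients with chronic obstructive pulmonary
    disease (COPD). Implements a class-conditional generative adversarial
    network for tabular records, distributional quality scores (per-feature
    Jensen-Shannon divergence and a Frechet distance on Gaussian moment
    summaries), interpretable if-then rule induction with covering and error
    statistics, Fisher's exact test validation of rules, and the
    baseline / candidate-augmented / augmented model workflow that accepts a
    synthetic dataset only when rules learned on it remain statistically
    valid on the real data. A multivariate Gaussian cohort simulator provides
    realistic correlated vital-sign records for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, jsonlite
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
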