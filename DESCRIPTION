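Package: eegformer
Title: Transformer-Based Classification of Psychiatric Conditions from Raw Resting-State EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying psychiatric conditions
    (major depressive disorder, ADHD, subjective memory complaints, OCD,
    healthy) from raw multichannel resting-state EEG. Provides the
    preprocessing chain (zero-phase Butterworth band-pass, decimation, edge
    cropping, per-channel z-scoring, overlapping epoching), a compact
    transformer-encoder classifier over raw time-by-electrode windows with
    multi-head scaled dot-product self-attention implemented and trained
    natively in R, three imbalance-aware training objectives (categorical
    cross-entropy, class-weighted cross-entropy, focal loss), cross-individual
    subject-stratified splitting with leakage guards, window-level to
    patient-level majority-vote aggregation, and a seeded synthetic EEG cohort
    generator with class-conditional band-power structure for testing the
    pipeline without access-restricted clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
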