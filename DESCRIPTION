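Package: pathbroker
Title: Honest-Broker Compilation and De-Identification of Digital Pathology Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for compiling de-identified whole-slide-image research
    datasets from a clinical digital pathology archive. Implements a
    consent-gated data warehouse over patients, cases, slides, images and
    pathology reports; HIPAA Safe-Harbor de-identification of structured
    records and free-text reports (date truncation, surrogate identifier
    generation with a persistent key store, rule-based text redaction);
    de-identification of SVS-style pyramidal TIFF whole-slide images by
    overwriting label and macro sub-images and masking sensitive metadata;
    screening of slide thumbnails for dark label-sticker bleed-through;
    deterministic post-scan quality-control triage with a rescan queue; and
    two-tier storage planning from access logs. A synthetic-fixture generator
    produces every input family with ground truth so the whole pipeline is
    exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'storage.R'
    'scan-qc.R'
    'tiff-lowlevel.R'
    'image-deid.R'
    'warehouse.R'
    'keystore.R'
    'text-deid.R'
    'fixtures.R'
    'phi-screen.R'
    'compile.R'
    'cli.R'
    'pathbroker-package.R'
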