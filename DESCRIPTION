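Package: fdtaudit
Title: Formal Decision Trace Auditing for Slice-Level Brain Tumor Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post hoc symbolic auditing of four-class brain-tumor slice
    classifiers (glioma, meningioma, pituitary, no tumor). Deterministic
    symbolic features (Otsu in-mask intensity variance, central y-band
    overlap, border-band Canny edge density) are extracted from 2D slices,
    neuroradiologic plausibility rules are encoded in quantifier-free
    linear real arithmetic and checked by a built-in satisfiability solver
    with unsat-core diagnosis, and every decision is recorded as a
    tamper-evident Formal Decision Trace artifact with SHA-256 attestation.
    Includes a synthetic phantom generator with analytically known feature
    ground truth, inverse-frequency class-weighted cross-entropy, a small
    trainable reference CNN, stratified partitioning and macro-averaged
    evaluation metrics, so the full predict-then-verify loop runs without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
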