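Package: tmascreen
Title: Automated Screening of Immunostained Tissue Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible digital-pathology pipeline for brightfield tissue
    microarrays (TMAs) immunostained with a nuclear marker such as MLH1.
    Implements colour deconvolution of haematoxylin/DAB stains from optical
    densities, positive cell detection with nucleus segmentation and cell
    expansion, Gaussian-smoothed neighbourhood features, a random-forest
    tissue-type classifier, TMA dearraying with density-based core validation,
    and a per-core certification decision tree that calls histology (normal
    epithelium versus tumour) and marker status (proficient versus deficient)
    at a configurable supermajority threshold, flagging ambiguous cores for
    manual review. Includes a synthetic TMA generator with per-cell ground
    truth so the whole pipeline can be exercised without external slide data,
    and diagnostic agreement statistics (exact binomial confidence intervals,
    Cohen's kappa) for validating calls against reference review.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    randomForest,
    mgcv,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
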