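Package: imspeaks
Title: Online Peak Extraction for MCC/IMS Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated online peak extraction for ion mobility
    spectrometry measurements coupled with multi-capillary columns (MCC/IMS).
    Each arriving spectrum is denoised and baseline-corrected with a
    three-component EM mixture, reduced to a list of scaled shifted
    inverse-Gaussian peak models, aligned to the previous spectrum's peak list
    by Needleman-Wunsch dynamic programming, and the resulting peak chains are
    merged into seven-parameter two-dimensional peak models.  Peaks from
    multiple measurements are grouped by an adaptive Gaussian-mixture EM that
    merges nearby clusters on the fly.  Includes synthetic-data generators for
    whole spectrum-chromatograms and for peak-location clouds, plus clustering
    quality scores (Fowlkes-Mallows index, normalized variation of
    information), so that every pipeline stage can be exercised without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
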