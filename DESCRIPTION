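Package: eegnorm
Title: Normative Brain Mapping from Scalp EEG Relative Band Power
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds normative maps of regional relative band power from
    source-localised resting-state scalp EEG and scores patient recordings
    against them. Provides sensor preprocessing (resampling, zero-phase
    bandpass, epoch selection), an sLORETA standardized minimum-norm inverse,
    sign-flip averaging of orientation-constrained sources into region time
    series, Welch spectral estimation with relative band power in the five
    classical bands, normative mean/SD maps with robustness, hemispheric
    symmetry and cross-modality comparisons, z-score abnormality mapping with
    a max-across-bands indicator, and ipsilateral/contralateral lateralization
    statistics for temporal-lobe epilepsy cohorts. Includes a synthetic-data
    generator (toy forward models, band-structured multi-subject EEG, injected
    regional abnormalities) so the full pipeline is testable end to end, plus
    EDF and BrainVision readers and delimited-table interchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
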