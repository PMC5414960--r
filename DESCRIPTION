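Package: passaggio
Title: Vocal Register Transition Analysis from Electroglottographic and
    High-Speed-Videoendoscopy-Derived Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying vocal register transitions (passaggi)
    in pitch glides from electroglottographic (EGG) recordings and from
    glottal segmentation outputs of high-speed videoendoscopy.  Implements
    dEGG-based glottal cycle separation, per-cycle Fourier descriptors and
    their cycle-based and window-based sample entropy (FDSE), EGG and dEGG
    wavegrams, glottal-area-waveform open quotient statistics over aligned
    25 ms analysis windows, spatio-temporal glottal opening/closing
    contours along the anterior-posterior axis, inter-rater intraclass
    correlation, and cohort-level regression summaries.  Includes a
    synthetic-data generator producing EGG pulse trains, glottal area
    waveforms, medio-lateral displacement fields and rater score matrices
    with programmable transition strategies for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
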