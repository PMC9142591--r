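Package: erppls
Title: Event-Related Potential Pipelines with Partial Least Squares Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, preprocessing and multivariate analysis of
    event-related potentials (ERPs) from multichannel EEG. Provides a
    synthetic-study generator (ERP templates, 1/f background noise, blink
    artifacts), the standard preprocessing chain (zero-phase band-pass
    filtering, ocular-artifact regression, detrending, epoching, baseline
    correction, amplitude- and response-based trial rejection, subject
    inclusion rules), extraction of N400 and P600 component windows as
    feature vectors, and Mean-Centered and Contrast Partial Least Squares
    (PLS) with permutation tests for group and condition differences,
    organised into reproducible analysis batteries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
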